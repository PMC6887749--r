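# Promoter extraction (2 kb upstream of the translation start site),
# sense-strand cis-element scanning, and promoter allele comparison.

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

iupac_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(c0) {
    opts <- IUPAC_DNA[[c0]]
    if (is.null(opts)) stop("non-IUPAC character in pattern: ", c0)
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Extract the promoter of a gene
#'
#' The promoter is `length` bp of genomic sequence immediately upstream of
#' the translation start site (the first CDS base on the coding strand),
#' read 5' to 3' on the gene's sense strand.  Promoters are truncated at
#' contig edges, with the truncation flagged.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param model A [gene_model()] object with a CDS.
#' @param length Promoter length in bp.
#' @return List of class `promoter_record`: `gene_id`, `sequence`,
#'   `length`, `truncated`, plus empty `element_counts` / `hit_positions`
#'   to be filled by [scan_cis_elements()].
#' @export
extract_promoter <- function(genome, model, length = 2000L) {
  if (is.null(model$cds) || nrow(model$cds) == 0L)
    stop("gene ", model$gene_id, " has no CDS; cannot locate the ",
         "translation start site")
  chrom <- genome[[model$chromosome]]
  if (is.null(chrom)) stop("chromosome ", model$chromosome, " not in genome")
  clen <- nchar(chrom)
  if (model$strand == "+") {
    tss <- min(model$cds[, 1])
    from <- max(1L, tss - length)
    to <- tss - 1L
    seq <- if (to >= from) substring(chrom, from, to) else ""
  } else {
    tss <- max(model$cds[, 2])
    from <- tss + 1L
    to <- min(clen, tss + length)
    seq <- if (to >= from) revcomp(substring(chrom, from, to)) else ""
  }
  structure(list(gene_id = model$gene_id, sequence = seq,
                 length = nchar(seq), truncated = nchar(seq) < length,
                 element_counts = NULL, hit_positions = NULL),
            class = "promoter_record")
}

count_element_hits <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")") # overlapping occurrences
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-regulatory elements
#'
#' IUPAC-aware substring matching on the sense strand only; overlapping
#' occurrences are all counted and 1-based offsets recorded.
#'
#' @param promoter A `promoter_record` (or a bare sequence string).
#' @param dictionary Data frame from [read_cis_elements()].
#' @param both_strands Also scan the reverse complement (off by default;
#'   sense-strand scanning is the survey convention).
#' @return The `promoter_record` with `element_counts` and `hit_positions`
#'   filled.
#' @export
scan_cis_elements <- function(promoter, dictionary, both_strands = FALSE) {
  if (is.character(promoter))
    promoter <- structure(list(gene_id = NA_character_, sequence = promoter,
                               length = nchar(promoter), truncated = FALSE),
                          class = "promoter_record")
  hits <- lapply(seq_len(nrow(dictionary)), function(r) {
    pos <- count_element_hits(promoter$sequence, dictionary$pattern[r])
    if (both_strands) {
      rc <- revcomp(promoter$sequence)
      pos_rc <- count_element_hits(rc, dictionary$pattern[r])
      pos <- sort(c(pos, nchar(promoter$sequence) -
                      (pos_rc + nchar(dictionary$pattern[r]) - 1L) + 1L))
    }
    pos
  })
  names(hits) <- dictionary$name
  promoter$hit_positions <- hits
  promoter$element_counts <- vapply(hits, length, integer(1))
  promoter
}

#' Compare two promoter alleles
#'
#' The alleles are globally aligned (nucleotide Needleman-Wunsch, affine
#' gaps); contiguous gap runs are reported as deletion segments with their
#' sequence, length and offset in the longer-at-that-point allele, and the
#' per-element scan counts of the two alleles are diffed into lost and
#' gained maps.  Swapping the alleles swaps lost and gained.
#'
#' @param allele_a,allele_b Promoter sequences (A is conventionally the
#'   reference / longer allele).
#' @param dictionary Cis-element dictionary, see [read_cis_elements()].
#' @param min_identity_pct Refuse the comparison below this alignment
#'   identity (the alignment is then not meaningful).
#' @return List of class `variant_comparison`: `deletion_segments` (data
#'   frame sequence/length/offset), `insertion_segments`, `lost_elements`,
#'   `gained_elements`, `identity_pct`.
#' @export
compare_promoter_alleles <- function(allele_a, allele_b, dictionary,
                                     min_identity_pct = 50) {
  if (!nzchar(allele_a) || !nzchar(allele_b))
    stop("both alleles must be non-empty")
  al <- align_global(allele_a, allele_b, matrix = dna_matrix(),
                     gap_open = 10, gap_extend = 0.5,
                     alphabet = c("A", "C", "G", "T"))
  if (al$identity_pct < min_identity_pct)
    stop(sprintf(paste0("alignment identity %.1f%% below %.1f%%; the ",
                        "sequences do not look like alleles of one promoter"),
                 al$identity_pct, min_identity_pct))
  rows_a <- strsplit(al$aligned_a, "")[[1]]
  rows_b <- strsplit(al$aligned_b, "")[[1]]

  gap_runs <- function(gaprow, otherrow, other_is_a) {
    pos_other <- cumsum(otherrow != "-")
    r <- rle(gaprow == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep))
      return(data.frame(sequence = character(0), length = integer(0),
                        offset = integer(0), stringsAsFactors = FALSE))
    do.call(rbind, lapply(keep, function(k) {
      cols <- starts[k]:ends[k]
      data.frame(
        sequence = paste(otherrow[cols], collapse = ""),
        length = length(cols),
        offset = pos_other[cols[1]],
        stringsAsFactors = FALSE)
    }))
  }
  deletions <- gap_runs(rows_b, rows_a, TRUE)   # present in A, absent in B
  insertions <- gap_runs(rows_a, rows_b, FALSE) # present in B, absent in A

  counts_a <- scan_cis_elements(allele_a, dictionary)$element_counts
  counts_b <- scan_cis_elements(allele_b, dictionary)$element_counts
  lost <- pmax(counts_a - counts_b, 0L)
  gained <- pmax(counts_b - counts_a, 0L)

  structure(list(deletion_segments = deletions,
                 insertion_segments = insertions,
                 lost_elements = lost[lost > 0L],
                 gained_elements = gained[gained > 0L],
                 identity_pct = al$identity_pct),
            class = "variant_comparison")
}
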