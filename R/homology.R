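# Family-member identification: local-alignment screen against seed query
# proteins, then confirmation of the nucleotide-binding-domain (NBD) motif
# triplet (Walker A, ABC signature, Walker B), then chromosomal naming.

#' Screen a proteome against seed query proteins
#'
#' A subject is retained if ANY query reaches both the identity and the
#' query-coverage threshold; the best-scoring passing alignment per subject
#' is recorded.
#'
#' @param queries Named character vector of seed query proteins.
#' @param proteome Named character vector of subject proteins.
#' @param min_identity_pct Minimum percent identity over alignment columns.
#' @param min_query_coverage Minimum aligned fraction of the query.
#' @param matrix,gap_open,gap_extend Passed to [align_local()].
#' @return Named list of `local_alignment` objects (best hit per retained
#'   subject), keyed by subject id.
#' @export
screen_candidates <- function(queries, proteome, min_identity_pct = 30,
                              min_query_coverage = 0.5,
                              matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  if (length(queries) == 0L) stop("at least one query is required")
  hits <- list()
  for (sid in names(proteome)) {
    best <- NULL
    for (qid in names(queries)) {
      al <- align_local(queries[[qid]], proteome[[sid]], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
      if (al$identity_pct >= min_identity_pct &&
          al$query_coverage >= min_query_coverage &&
          (is.null(best) || al$score > best$score)) {
        al$query_id <- qid
        al$subject_id <- sid
        best <- al
      }
    }
    if (!is.null(best)) hits[[sid]] <- best
  }
  hits
}

#' Confirm the NBD motif triplet in a protein
#'
#' Searches left to right for a Walker A motif (`[AG]-x(4)-G-K-[ST]`), then
#' an ABC signature (`LSGGQ`, at most one mismatch) downstream of it, then a
#' Walker B motif (four hydrophobic residues from `{I,L,V,F,M,A}` followed
#' by `DE`) downstream of the signature.  `confirmed` requires all three in
#' N-to-C order; leftmost qualifying matches are reported.
#'
#' @param protein Protein sequence.
#' @param signature_max_mismatch Mismatch tolerance for the signature.
#' @return List of class `domain_evidence` with 1-based intervals
#'   `walker_a`, `signature`, `walker_b` (or `NULL` when absent) and a
#'   `confirmed` flag.
#' @export
confirm_domain <- function(protein, signature_max_mismatch = 1L) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  s <- toupper(protein)
  n <- nchar(s)

  wa <- regexpr("[AG].{4}GK[ST]", s, perl = TRUE)
  walker_a <- if (wa > 0) c(start = as.integer(wa), end = as.integer(wa) + 7L)

  signature <- NULL
  if (!is.null(walker_a)) {
    from <- walker_a["end"] + 1L
    sig <- c("L", "S", "G", "G", "Q")
    ch <- strsplit(s, "")[[1]]
    if (n - from + 1L >= 5L) {
      for (p in seq.int(from, n - 4L)) {
        if (sum(ch[p:(p + 4L)] != sig) <= signature_max_mismatch) {
          signature <- c(start = p, end = p + 4L)
          break
        }
      }
    }
  }

  walker_b <- NULL
  if (!is.null(signature)) {
    rest <- substring(s, signature[["end"]] + 1L)
    wb <- regexpr("[ILVFMA]{4}DE", rest, perl = TRUE)
    if (wb > 0) {
      st <- signature[["end"]] + as.integer(wb)
      walker_b <- c(start = st, end = st + 5L)
    }
  }

  structure(list(walker_a = walker_a, signature = signature,
                 walker_b = walker_b,
                 confirmed = !is.null(walker_a) && !is.null(signature) &&
                   !is.null(walker_b)),
            class = "domain_evidence")
}

#' Name family members by chromosomal position
#'
#' Members are sorted by chromosome (natural order, so chr2 precedes chr10)
#' and then by start coordinate, and named `prefix1 .. prefixN`.  The result
#' is independent of input order.
#'
#' @param members Character vector of member gene ids.
#' @param models Named list of [gene_model()] objects covering the members.
#' @param prefix Name prefix, e.g. `"SynABC"`.
#' @return Named character vector: gene id -> family name.
#' @export
assign_names <- function(members, models, prefix) {
  missing <- setdiff(members, names(models))
  if (length(missing))
    stop("member without a gene model: ", paste(missing, collapse = ", "))
  chrom <- vapply(models[members], `[[`, character(1), "chromosome")
  start <- vapply(models[members], `[[`, integer(1), "start")
  chr_levels <- unique(chrom)[natural_chrom_order(unique(chrom))]
  ord <- order(match(chrom, chr_levels), start)
  stats::setNames(paste0(prefix, seq_along(members)), members[ord])
}

#' Identify family members in a proteome
#'
#' Composes [screen_candidates()] and [confirm_domain()]: a member is a
#' screened candidate whose protein carries the confirmed NBD motif triplet.
#'
#' @inheritParams screen_candidates
#' @return List with `members` (character vector), `hits` (screen output)
#'   and `evidence` (per-candidate `domain_evidence`).
#' @export
identify_family <- function(queries, proteome, min_identity_pct = 30,
                            min_query_coverage = 0.5, matrix = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  hits <- screen_candidates(queries, proteome, min_identity_pct,
                            min_query_coverage, matrix, gap_open, gap_extend)
  evidence <- lapply(proteome[names(hits)], confirm_domain)
  members <- names(hits)[vapply(evidence, `[[`, logical(1), "confirmed")]
  list(members = members, hits = hits, evidence = evidence)
}
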