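# GFF3 reading/writing and the gene model container.
#
# Coordinates are 1-based inclusive everywhere (GFF3 convention); any
# half-open arithmetic is internal and never serialized.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Sequence (chromosome/scaffold) identifier.
#' @param strand `"+"` or `"-"`.
#' @param start,end Gene span, 1-based inclusive.
#' @param exons Two-column matrix (start, end) of exon intervals, sorted in
#'   genome coordinates, non-overlapping.
#' @param cds Two-column matrix of CDS intervals; must lie within the exons.
#' @param utr5 Optional two-column matrix of 5' UTR intervals.
#' @param rank Ordinal position of the gene on its chromosome (assigned by
#'   [read_gff3()] after sorting).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end,
                       exons, cds, utr5 = NULL, rank = NA_integer_) {
  stopifnot(strand %in% c("+", "-"), start <= end)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) < 1L) stop("gene ", gene_id, " has zero exons")
  if (any(exons[, 1] > exons[, 2])) stop("invalid exon interval in ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in ", gene_id)
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  for (k in seq_len(nrow(cds))) {
    inside <- any(cds[k, 1] >= exons[, 1] & cds[k, 2] <= exons[, 2])
    if (!inside)
      stop("CDS outside exon span in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, cds = cds, utr5 = utr5,
                 rank = as.integer(rank)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d cds_parts=%d rank=%s\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), nrow(x$cds), x$rank))
  invisible(x)
}

# natural-order key for chromosome names: "chr2" sorts before "chr10"
natural_chrom_order <- function(chroms) {
  num <- suppressWarnings(as.numeric(gsub("\\D", "", chroms)))
  num[is.na(num)] <- Inf
  order(num, chroms)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS features linked by `Parent` attributes
#' (single-transcript genes).  Models are returned sorted by chromosome
#' (natural order) and start, with `rank` assigned 1..n per chromosome.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [gene_model()] objects, keyed by gene id.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR"), , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)

  first_parent <- function(p) {
    out <- vapply(p, function(v) if (length(v)) as.character(v)[1] else NA_character_,
                  character(1))
    out
  }
  mrnas$parent_id <- first_parent(mrnas$Parent)
  parts$parent_id <- first_parent(parts$Parent)
  if (anyNA(mrnas$parent_id) || anyNA(parts$parent_id))
    stop("feature without Parent attribute in ", path)

  mrna2gene <- stats::setNames(mrnas$parent_id, mrnas$ID)
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- as.character(g$ID)
    tids <- mrnas$ID[mrnas$parent_id == gid]
    gp <- parts[parts$parent_id %in% tids, , drop = FALSE]
    ex <- gp[gp$type == "exon", c("start", "end"), drop = FALSE]
    cd <- gp[gp$type == "CDS", c("start", "end"), drop = FALSE]
    u5 <- gp[gp$type == "five_prime_UTR", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0L) stop("gene ", gid, " has no exon features")
    models[[i]] <- gene_model(
      gene_id = gid, chromosome = g$seqnames, strand = g$strand,
      start = g$start, end = g$end,
      exons = as.matrix(ex), cds = as.matrix(cd),
      utr5 = if (nrow(u5)) as.matrix(u5) else NULL)
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")

  chroms <- vapply(models, `[[`, character(1), "chromosome")
  starts <- vapply(models, `[[`, integer(1), "start")
  chr_levels <- unique(chroms)[natural_chrom_order(unique(chroms))]
  ord <- order(match(chroms, chr_levels), starts)
  models <- models[ord]
  chroms <- chroms[ord]
  for (ch in chr_levels) {
    idx <- which(chroms == ch)
    for (k in seq_along(idx)) models[[idx[k]]]$rank <- k
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS (and five_prime_UTR where present) features with
#' `Parent` links, one transcript per gene, in deterministic order.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tfamsurvey\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  for (m in models) {
    tid <- paste0(m$gene_id, ".t1")
    writeLines(fmt(m$chromosome, "gene", m$start, m$end, m$strand,
                   paste0("ID=", m$gene_id)), con)
    writeLines(fmt(m$chromosome, "mRNA", m$start, m$end, m$strand,
                   paste0("ID=", tid, ";Parent=", m$gene_id)), con)
    for (k in seq_len(nrow(m$exons)))
      writeLines(fmt(m$chromosome, "exon", m$exons[k, 1], m$exons[k, 2],
                     m$strand, paste0("ID=", tid, ".exon", k, ";Parent=", tid)),
                 con)
    if (!is.null(m$utr5))
      for (k in seq_len(nrow(m$utr5)))
        writeLines(fmt(m$chromosome, "five_prime_UTR", m$utr5[k, 1],
                       m$utr5[k, 2], m$strand,
                       paste0("ID=", tid, ".utr5.", k, ";Parent=", tid)), con)
    for (k in seq_len(nrow(m$cds)))
      writeLines(fmt(m$chromosome, "CDS", m$cds[k, 1], m$cds[k, 2],
                     m$strand, paste0("ID=", tid, ".cds", k, ";Parent=", tid)),
                 con)
  }
  invisible(path)
}
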