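# Gene structure statistics, chromosomal localization tables, and the
# tandem / segmental duplication classification.

#' Exon/intron statistics for one gene model
#'
#' @param model A [gene_model()] object.
#' @return List with `exon_count`, `intron_count`, `intronless`.
#' @export
gene_structure_stats <- function(model) {
  ne <- nrow(model$exons)
  if (ne == 0L) stop("gene ", model$gene_id, " has zero exons")
  list(exon_count = ne, intron_count = ne - 1L, intronless = ne == 1L)
}

canonical_pair <- function(a, b) {
  if (a <= b) c(a, b) else c(b, a)
}

# count ALL annotated genes strictly between two members on one chromosome
intervening_count <- function(model_a, model_b) {
  abs(model_a$rank - model_b$rank) - 1L
}

#' Detect tandemly duplicated gene pairs
#'
#' A pair qualifies if both genes lie on the same chromosome with at most
#' one intervening annotated gene (counting every annotated gene, not only
#' family members) and their proteins reach `min_identity_pct` under global
#' alignment.  A gene may take part in several pairs (tandem arrays).
#'
#' @param members Character vector of member gene ids.
#' @param models Named list of [gene_model()] objects for ALL annotated
#'   genes (so intervening counts are correct), with ranks assigned.
#' @param proteome Named character vector of proteins for the members.
#' @param min_identity_pct Identity threshold (percent).
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return Data frame with columns `gene_a`, `gene_b`, `mode`,
#'   `identity_pct`, `intervening`, `chrom_a`, `chrom_b`, canonically
#'   ordered (`gene_a < gene_b`, rows sorted).
#' @export
detect_tandem <- function(members, models, proteome, min_identity_pct = 70,
                          matrix = blosum62(), gap_open = 11, gap_extend = 1) {
  missing <- setdiff(members, names(models))
  if (length(missing))
    stop("member without a gene model: ", paste(missing, collapse = ", "))
  rows <- list()
  members <- sort(members)
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (j <= i) next
      ma <- models[[members[i]]]; mb <- models[[members[j]]]
      if (ma$chromosome != mb$chromosome) next
      iv <- intervening_count(ma, mb)
      if (iv > 1L) next
      al <- align_global(proteome[[members[i]]], proteome[[members[j]]],
                         matrix = matrix, gap_open = gap_open,
                         gap_extend = gap_extend)
      if (al$identity_pct < min_identity_pct) next
      pr <- canonical_pair(members[i], members[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pr[1], gene_b = pr[2], mode = "tandem",
        identity_pct = al$identity_pct, intervening = iv,
        chrom_a = ma$chromosome, chrom_b = mb$chromosome,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               mode = character(0), identity_pct = numeric(0),
               intervening = integer(0), chrom_a = character(0),
               chrom_b = character(0), stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Detect segmentally duplicated gene pairs
#'
#' All-against-all global alignment among members: a pair qualifies if its
#' identity strictly exceeds `min_identity_pct`, both-direction coverage
#' reaches `min_mutual_coverage`, and the pair is not already classified
#' tandem (the two sets are disjoint by construction).
#'
#' @inheritParams detect_tandem
#' @param tandem Data frame from [detect_tandem()] (pairs to exclude).
#' @param min_mutual_coverage Minimum aligned fraction of each protein.
#' @return Data frame in the same layout as [detect_tandem()], with
#'   `mode = "segmental"` and `intervening = NA`.
#' @export
detect_segmental <- function(members, models, proteome, tandem = NULL,
                             min_identity_pct = 80, min_mutual_coverage = 0.5,
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  tandem_keys <- if (!is.null(tandem) && nrow(tandem))
    paste(tandem$gene_a, tandem$gene_b) else character(0)
  members <- sort(members)
  rows <- list()
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (j <= i) next
      pr <- canonical_pair(members[i], members[j])
      if (paste(pr[1], pr[2]) %in% tandem_keys) next
      al <- align_global(proteome[[members[i]]], proteome[[members[j]]],
                         matrix = matrix, gap_open = gap_open,
                         gap_extend = gap_extend)
      if (!(al$identity_pct > min_identity_pct)) next
      if (al$coverage_a < min_mutual_coverage ||
          al$coverage_b < min_mutual_coverage) next
      ma <- models[[members[i]]]; mb <- models[[members[j]]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pr[1], gene_b = pr[2], mode = "segmental",
        identity_pct = al$identity_pct, intervening = NA_integer_,
        chrom_a = ma$chromosome, chrom_b = mb$chromosome,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               mode = character(0), identity_pct = numeric(0),
               intervening = integer(0), chrom_a = character(0),
               chrom_b = character(0), stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Per-chromosome localization table for family members
#'
#' @param members Character vector of member gene ids.
#' @param models Named list of [gene_model()] objects.
#' @param family_names Optional named vector gene id -> family name.
#' @return Data frame (chromosome, start, end, strand, gene_id,
#'   family_name), grouped by chromosome in natural order, sorted by start.
#' @export
chromosome_map <- function(members, models, family_names = NULL) {
  if (length(members) == 0L)
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), family_name = character(0),
                      stringsAsFactors = FALSE))
  tab <- data.frame(
    chromosome = vapply(models[members], `[[`, character(1), "chromosome"),
    start = vapply(models[members], `[[`, integer(1), "start"),
    end = vapply(models[members], `[[`, integer(1), "end"),
    strand = vapply(models[members], `[[`, character(1), "strand"),
    gene_id = members,
    family_name = if (is.null(family_names)) NA_character_
                  else unname(family_names[members]),
    stringsAsFactors = FALSE)
  levels <- unique(tab$chromosome)[natural_chrom_order(unique(tab$chromosome))]
  tab <- tab[order(match(tab$chromosome, levels), tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
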