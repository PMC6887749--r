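# End-to-end survey orchestration: identify -> characterize -> phylogeny ->
# structure/duplication -> motifs/promoters (-> expression), with a
# parameter manifest and a summary report.

#' Summarize per-species member counts
#'
#' @param counts Named integer vector (or data frame with columns `species`,
#'   `n_members`) of per-species family sizes.
#' @return List with `per_species` (named vector) and `grand_total`.
#' @export
member_count_summary <- function(counts) {
  if (is.data.frame(counts))
    counts <- stats::setNames(as.integer(counts$n_members), counts$species)
  list(per_species = counts, grand_total = sum(counts))
}

#' Run the full survey pipeline
#'
#' Stages: member identification (local-alignment screen + NBD
#' confirmation), naming, protein characterization, phylogeny with
#' bootstrap and subfamily assignment, exon/intron and duplication
#' classification, motif scanning, promoter element scanning.  All
#' artifacts and a manifest of every parameter in effect are written under
#' `out_dir`; a rerun with the same config is byte-identical.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Required keys: `genome`, `gff3`, `proteome`, `queries` (FASTA/GFF3
#'   paths); optional: `motif_table`, `element_dictionary`, `prefix`,
#'   `min_identity_pct`, `min_query_coverage`, `tandem_min_identity_pct`,
#'   `segmental_min_identity_pct`, `bootstrap_replicates`, `seed`,
#'   `reference_subfamilies` (named list leaf -> subfamily).
#' @param out_dir Output directory.
#' @return The survey report (list), invisibly written as
#'   `report.json` and `report.txt` with all stage tables.
#' @export
run_survey <- function(config, out_dir = "survey_out") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- c("genome", "gff3", "proteome", "queries")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys))
    stop("config is missing required keys: ",
         paste(missing_keys, collapse = ", "))
  for (k in need)
    if (!file.exists(cfg[[k]])) stop("config input does not exist: ", cfg[[k]])
  defaults <- list(prefix = "SynABC", min_identity_pct = 30,
                   min_query_coverage = 0.5, tandem_min_identity_pct = 70,
                   segmental_min_identity_pct = 80,
                   segmental_min_mutual_coverage = 0.5,
                   bootstrap_replicates = 100L, seed = 1L,
                   max_mismatch_fraction = 0.1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- read_fasta(cfg$genome)
  models <- read_gff3(cfg$gff3)
  proteome <- read_fasta(cfg$proteome)
  queries <- read_fasta(cfg$queries)

  # 1. identify
  idres <- identify_family(queries, proteome,
                           min_identity_pct = cfg$min_identity_pct,
                           min_query_coverage = cfg$min_query_coverage)
  members <- sort(idres$members)
  fam_names <- assign_names(members, models, cfg$prefix)

  # 2. characterize
  props <- lapply(proteome[members], compute_properties)
  classes <- lapply(props, classify_protein)
  char_report <- characterization_report(classes)
  char_tab <- data.frame(
    gene_id = members,
    family_name = unname(fam_names[members]),
    length = vapply(props, `[[`, integer(1), "length"),
    mw = vapply(props, `[[`, numeric(1), "mw"),
    pi = vapply(props, `[[`, numeric(1), "pi"),
    n_negative = vapply(props, `[[`, integer(1), "n_negative"),
    n_positive = vapply(props, `[[`, integer(1), "n_positive"),
    instability_index = vapply(props, `[[`, numeric(1), "instability_index"),
    aliphatic_index = vapply(props, `[[`, numeric(1), "aliphatic_index"),
    gravy = vapply(props, `[[`, numeric(1), "gravy"),
    n_tm_segments = vapply(props, function(p) nrow(p$tm_segments), integer(1)),
    pi_class = vapply(classes, `[[`, character(1), "pi_class"),
    stability = vapply(classes, `[[`, character(1), "stability"),
    hydropathy = vapply(classes, `[[`, character(1), "hydropathy"),
    stringsAsFactors = FALSE)
  utils::write.table(char_tab, file.path(out_dir, "characterization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 3. phylogeny (members + queries as references)
  subfam <- NULL
  tree_res <- NULL
  if (length(members) >= 2L) {
    aln <- progressive_msa(c(proteome[members], queries))
    tree_res <- bootstrap_supports(aln, cfg$bootstrap_replicates,
                                   seed = cfg$seed)
    ape::write.tree(tree_res$tree, file.path(out_dir, "family_nj.nwk"))
    refs <- cfg$reference_subfamilies
    if (is.null(refs)) refs <- stats::setNames(names(queries), names(queries))
    subfam <- assign_subfamilies(tree_res$tree, unlist(refs))
    subfam <- subfam[members]
  }

  # 4. structure and duplications
  stats_tab <- do.call(rbind, lapply(members, function(id) {
    st <- gene_structure_stats(models[[id]])
    data.frame(gene_id = id, exon_count = st$exon_count,
               intron_count = st$intron_count, intronless = st$intronless,
               stringsAsFactors = FALSE)
  }))
  tandem <- detect_tandem(members, models, proteome,
                          min_identity_pct = cfg$tandem_min_identity_pct)
  segmental <- detect_segmental(members, models, proteome, tandem = tandem,
                                min_identity_pct = cfg$segmental_min_identity_pct,
                                min_mutual_coverage = cfg$segmental_min_mutual_coverage)
  dup <- rbind(tandem, segmental)
  utils::write.table(dup, file.path(out_dir, "duplication_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  locmap <- chromosome_map(members, models, fam_names)
  utils::write.table(locmap, file.path(out_dir, "localization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 5. motifs and promoters
  motif_stats <- NULL
  if (!is.null(cfg$motif_table)) {
    motifs <- read_motif_table(cfg$motif_table)
    motif_stats <- motif_width_stats(motifs)
    hits <- do.call(rbind, lapply(members, function(id) {
      h <- scan_protein_motifs(proteome[[id]], motifs,
                               cfg$max_mismatch_fraction)
      if (nrow(h)) cbind(gene_id = id, h) else NULL
    }))
    if (!is.null(hits))
      utils::write.table(hits, file.path(out_dir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  element_matrix <- NULL
  if (!is.null(cfg$element_dictionary)) {
    dict <- read_cis_elements(cfg$element_dictionary)
    proms <- lapply(members, function(id)
      scan_cis_elements(extract_promoter(genome, models[[id]]), dict))
    element_matrix <- do.call(rbind, lapply(proms, `[[`, "element_counts"))
    rownames(element_matrix) <- members
    utils::write.table(
      data.frame(gene_id = members, element_matrix, check.names = FALSE),
      file.path(out_dir, "promoter_elements.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    n_members = length(members),
    members = members,
    family_names = as.list(fam_names),
    characterization = char_report,
    subfamily_sizes = if (!is.null(subfam)) as.list(table(subfam)) else NULL,
    intronless_count = sum(stats_tab$intronless),
    intronless = stats_tab$gene_id[stats_tab$intronless],
    tandem_pair_count = nrow(tandem),
    segmental_pair_count = nrow(segmental),
    motif_stats = motif_stats,
    element_totals = if (!is.null(element_matrix))
      as.list(colSums(element_matrix)) else NULL,
    parameters = cfg[setdiff(names(cfg), need)])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- c(sprintf("family members: %d", report$n_members),
           sprintf("intronless: %d", report$intronless_count),
           sprintf("tandem pairs: %d", report$tandem_pair_count),
           sprintf("segmental pairs: %d", report$segmental_pair_count),
           sprintf("pI classes (acidic/neutral/basic): %s",
                   paste(char_report$pi, collapse = "/")),
           sprintf("stability (stable/instable): %s",
                   paste(char_report$stability, collapse = "/")))
  writeLines(txt, file.path(out_dir, "report.txt"))
  jsonlite::write_json(report$parameters, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
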