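# Tabular readers: consensus motif tables, cis-element dictionaries,
# truth tables from the synthetic generator, expression matrices.

MOTIF_CONSENSUS_CHARS <- c(AA1, "B", "Z", "J", "X")

#' Read an extended-alphabet protein motif table
#'
#' TSV columns: `motif_id`, `consensus`, `evalue` (kept as opaque text —
#' printed E-values routinely underflow doubles), `sites`, and optionally
#' `width`.  Width is always recomputed from the consensus string; a
#' disagreeing declared width is an error.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `motif_id`, `consensus`, `evalue_text`,
#'   `sites`, `width`, of class `motif_table`.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  need <- c("motif_id", "consensus")
  if (!all(need %in% names(tab)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  cons <- toupper(tab$consensus)
  bad <- vapply(strsplit(cons, ""), function(ch)
    any(!ch %in% MOTIF_CONSENSUS_CHARS), logical(1))
  if (any(bad))
    stop("motif ", tab$motif_id[bad][1],
         " contains characters outside the extended amino-acid alphabet")
  width <- nchar(cons)
  if (any(width < 6L | width > 200L))
    stop("motif widths must lie in [6, 200]")
  if ("width" %in% names(tab)) {
    declared <- as.integer(tab$width)
    if (any(declared != width, na.rm = TRUE)) {
      off <- which(declared != width)[1]
      stop("motif ", tab$motif_id[off], ": declared width ", declared[off],
           " disagrees with consensus length ", width[off])
    }
  }
  out <- data.frame(
    motif_id = tab$motif_id, consensus = cons,
    evalue_text = if ("evalue" %in% names(tab)) tab$evalue else NA_character_,
    sites = if ("sites" %in% names(tab)) as.integer(tab$sites) else NA_integer_,
    width = width, stringsAsFactors = FALSE)
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Read a cis-regulatory element dictionary
#'
#' TSV columns: `name`, `pattern` (uppercase IUPAC nucleotide string),
#' `category` (one of stress / phytohormone / other).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `name`, `pattern`, `category`.
#' @export
read_cis_elements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "pattern", "category")
  if (!all(need %in% names(tab)))
    stop("element dictionary must have columns: ", paste(need, collapse = ", "))
  tab$pattern <- toupper(tab$pattern)
  if (any(!nzchar(tab$pattern))) stop("empty cis-element pattern")
  bad <- vapply(strsplit(tab$pattern, ""), function(ch)
    any(!ch %in% names(IUPAC_DNA)), logical(1))
  if (any(bad))
    stop("element ", tab$name[bad][1], " has a non-IUPAC pattern")
  if (any(!tab$category %in% c("stress", "phytohormone", "other")))
    stop("element category must be stress, phytohormone, or other")
  tab[need]
}

#' Read the truth tables emitted by the synthetic generator
#'
#' @param dir Directory containing `truth_*.tsv` files written by
#'   [generate_survey_dataset()].
#' @return A list with elements `family_members`, `tandem_pairs`,
#'   `segmental_pairs`, `intronless`, `element_counts`, `subfamily`.
#' @export
read_truth_tables <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, paste0("truth_", name, ".tsv"))
    if (!file.exists(p)) stop("missing truth table: ", p)
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  fam <- rd("family_members")
  list(
    family_members = fam$gene_id,
    subfamily = stats::setNames(fam$subfamily, fam$gene_id),
    tandem_pairs = rd("tandem_pairs"),
    segmental_pairs = rd("segmental_pairs"),
    intronless = rd("intronless")$gene_id,
    element_counts = rd("element_counts"))
}

#' Read a genes-by-samples expression matrix from CSV
#'
#' First column is the gene id; remaining columns are samples.  Missing
#' values must be explicit (`NA`), never silently zero.
#'
#' @param path Path to the CSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  m
}
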