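#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; record order is preserved.  Duplicate ids and
#' empty records are rejected rather than repaired.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", ids[!nzchar(seqs)][1])
  stats::setNames(seqs, ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) == 0 || !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    writeLines(paste0(">", names(seqs)[i]), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
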