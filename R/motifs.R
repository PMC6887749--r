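# Extended-alphabet consensus motif scanning on proteins.
#
# Consensus strings use the 20 amino acids plus B = {N,D}, Z = {Q,E},
# J = {I,L} and X = any.  Hits are non-overlapping per motif (leftmost
# greedy), MEME-site style.

motif_allowed_sets <- function(consensus) {
  lapply(strsplit(consensus, "")[[1]], function(c0) {
    if (c0 %in% names(MOTIF_ALPHABET)) MOTIF_ALPHABET[[c0]] else c0
  })
}

#' Scan a protein with consensus motifs
#'
#' A window matches when its mismatch count is at most
#' `floor(width * max_mismatch_fraction)`.  For each motif, hits are taken
#' left to right without overlap; the combined hit list is returned in
#' N-to-C order (the "motif array").
#'
#' @param protein Protein sequence.
#' @param motifs A `motif_table` from [read_motif_table()], or a data frame
#'   with columns `motif_id` and `consensus`.
#' @param max_mismatch_fraction Mismatch budget as a fraction of width.
#' @return Data frame with columns `motif_id`, `start`, `end`,
#'   `mismatches`, sorted by `start`.
#' @export
scan_protein_motifs <- function(protein, motifs, max_mismatch_fraction = 0.1) {
  ch <- strsplit(toupper(protein), "")[[1]]
  n <- length(ch)
  rows <- list()
  for (r in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[r]
    w <- nchar(cons)
    if (w > n) next
    allowed <- motif_allowed_sets(cons)
    budget <- floor(w * max_mismatch_fraction)
    # mism[k, p]: does window starting at p mismatch at offset k?
    nwin <- n - w + 1L
    mism <- matrix(FALSE, nrow = w, ncol = nwin)
    for (k in seq_len(w))
      mism[k, ] <- !(ch[k:(k + nwin - 1L)] %in% allowed[[k]])
    counts <- colSums(mism)
    p <- 1L
    while (p <= nwin) {
      if (counts[p] <= budget) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = motifs$motif_id[r], start = p, end = p + w - 1L,
          mismatches = as.integer(counts[p]), stringsAsFactors = FALSE)
        p <- p + w # leftmost greedy, non-overlapping
      } else p <- p + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), start = integer(0), end = integer(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Width statistics of a motif set
#'
#' @param motifs A motif table (see [scan_protein_motifs()]).
#' @return List with `count`, `min_width`, `max_width` (recomputed from the
#'   consensus strings).
#' @export
motif_width_stats <- function(motifs) {
  if (is.null(motifs) || nrow(motifs) == 0L) stop("empty motif list")
  w <- nchar(motifs$consensus)
  list(count = nrow(motifs), min_width = min(w), max_width = max(w))
}
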