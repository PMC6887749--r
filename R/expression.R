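# Hormone-induction and tissue-expression summaries: delta-delta-Ct fold
# changes, log2 fold-change matrices, induction calls.

#' 2^-ddCt fold change from raw Ct values
#'
#' `fold = 2^-[(Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)]`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Cycle-threshold values (finite numbers; vectorized).
#' @return Fold change(s) relative to control.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' log2 fold-change matrix
#'
#' `log2((treated + pseudocount) / (control + pseudocount))`, elementwise.
#' Swapping the arguments negates the result exactly.
#'
#' @param treated,control Matching genes-by-samples numeric matrices.
#' @param pseudocount Added to both matrices before the ratio (0 for qPCR
#'   relative values; use a small positive value for array signals).
#' @return Signed matrix of the same shape.
#' @export
log2fc_matrix <- function(treated, control, pseudocount = 0) {
  if (!all(dim(treated) == dim(control)))
    stop("treated and control matrices must have identical shapes")
  log2((treated + pseudocount) / (control + pseudocount))
}

#' Call hormone induction from fold-change profiles
#'
#' A gene is called induced under a treatment when any timepoint reaches
#' `threshold_fold` (inclusive); the maximizing timepoint is recorded.
#'
#' @param folds Named numeric vector of fold changes per timepoint, or a
#'   genes-by-timepoints matrix.
#' @param threshold_fold Induction threshold (fold, >= convention).
#' @return For a vector: list with `induced`, `peak_fold`,
#'   `peak_timepoint`.  For a matrix: data frame with one row per gene.
#' @export
call_induced <- function(folds, threshold_fold = 2) {
  if (is.matrix(folds)) {
    out <- do.call(rbind, lapply(rownames(folds), function(g) {
      r <- call_induced(folds[g, ], threshold_fold)
      data.frame(gene = g, induced = r$induced, peak_fold = r$peak_fold,
                 peak_timepoint = r$peak_timepoint, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (length(folds) < 1L) stop("at least one timepoint is required")
  peak <- which.max(folds)
  list(induced = folds[[peak]] >= threshold_fold,
       peak_fold = unname(folds[[peak]]),
       peak_timepoint = if (!is.null(names(folds))) names(folds)[peak]
                        else peak)
}
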