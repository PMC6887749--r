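# ProtParam-style protein characterization: average molecular weight,
# isoelectric point (Bjellqvist pKa set, bisection), charged-residue counts,
# elemental formula, instability index (Guruprasad), aliphatic index
# (Ikai), GRAVY (Kyte-Doolittle), plus a transparent hydropathy-window
# transmembrane caller.

aa_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), AA1)
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "),
         " (the 20 standard amino acids are required here)")
  table(factor(ch, levels = AA1))
}

# signed net charge at a given pH for a composition (vectorized over pH)
net_charge <- function(counts, pH) {
  pos <- PKA_SET$positive
  neg <- PKA_SET$negative
  q <- rep(0, length(pH))
  ncount <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(ncount) <- c("Nterm", "K", "R", "H")
  for (g in names(pos))
    q <- q + ncount[[g]] / (1 + 10^(pH - pos[[g]]))
  ccount <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(ccount) <- c("Cterm", "D", "E", "C", "Y")
  for (g in names(neg))
    q <- q - ccount[[g]] / (1 + 10^(neg[[g]] - pH))
  q
}

isoelectric_point <- function(counts, tol = 1e-4) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH; bisect to |charge| < tol
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Compute ProtParam-style physicochemical properties
#'
#' @param seq Protein sequence over the 20 standard amino acids (no `X`).
#' @param tm_window,tm_cutoff Passed to [predict_tm_segments()].
#' @return A list of class `protein_properties`: `length`, `mw` (average
#'   daltons), `pi`, `n_negative` (Asp+Glu), `n_positive` (Arg+Lys),
#'   `formula` (named C/H/N/O/S counts), `instability_index`,
#'   `aliphatic_index`, `gravy`, `tm_segments`.
#' @export
compute_properties <- function(seq, tm_window = 19L, tm_cutoff = 1.6) {
  seq <- toupper(seq)
  counts <- aa_counts(seq)
  n <- sum(counts)

  mw <- sum(counts * RESIDUE_MASS[AA1]) + WATER_MASS
  formula <- colSums(RESIDUE_FORMULA * as.vector(counts)) +
    c(C = 0, H = 2, N = 0, O = 1, S = 0) # one water

  ch <- strsplit(seq, "")[[1]]
  ii <- if (n >= 2L) {
    diwv <- diwv_table()
    (10 / n) * sum(diwv[cbind(ch[-n], ch[-1L])])
  } else 0
  molpct <- 100 * counts / n
  ai <- molpct[["A"]] + 2.9 * molpct[["V"]] +
    3.9 * (molpct[["I"]] + molpct[["L"]])
  gravy <- sum(counts * KD_HYDROPATHY[AA1]) / n

  structure(list(
    length = as.integer(n), mw = mw, pi = isoelectric_point(counts),
    n_negative = as.integer(counts[["D"]] + counts[["E"]]),
    n_positive = as.integer(counts[["R"]] + counts[["K"]]),
    formula = formula, instability_index = ii, aliphatic_index = ai,
    gravy = gravy,
    tm_segments = predict_tm_segments(seq, tm_window, tm_cutoff)),
    class = "protein_properties")
}

#' Predict transmembrane segments by hydropathy windows
#'
#' A transparent Kyte-Doolittle sliding-window caller: every window of
#' `window` residues with mean hydropathy at or above `cutoff` marks its
#' span; overlapping spans are merged.  This is a deliberately simple
#' stand-in for HMM-based predictors and is labelled as such in reports.
#'
#' @param seq Protein sequence.
#' @param window Window width in residues.
#' @param cutoff Mean-hydropathy threshold.
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive);
#'   zero rows when no window qualifies.
#' @export
predict_tm_segments <- function(seq, window = 19L, cutoff = 1.6) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (n < window) return(empty)
  h <- KD_HYDROPATHY[ch]
  if (anyNA(h)) stop("unknown residue in transmembrane scan")
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hitstart <- which(means >= cutoff)
  if (!length(hitstart)) return(empty)
  spans <- cbind(start = hitstart, end = hitstart + window - 1L)
  merged <- list(spans[1, ])
  for (k in seq_len(nrow(spans))[-1]) {
    last <- merged[[length(merged)]]
    if (spans[k, 1] <= last[2]) {
      last[2] <- max(last[2], spans[k, 2])
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- spans[k, ]
  }
  out <- do.call(rbind, merged)
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Classify a characterized protein
#'
#' pI class uses open bands: acidic below `acidic_max`, basic above
#' `basic_min`, neutral between.  Stability uses the published strict
#' threshold (instability index above 40 means instable); hydropathy is
#' hydrophilic for strictly negative GRAVY.
#'
#' @param props A `protein_properties` object.
#' @param acidic_max,basic_min pI class boundaries.
#' @return List of class `protein_classification` with `pi_class`,
#'   `stability`, `hydropathy`, `has_tm`.
#' @export
classify_protein <- function(props, acidic_max = 6.5, basic_min = 7.5) {
  stopifnot(acidic_max < basic_min)
  structure(list(
    pi_class = if (props$pi < acidic_max) "acidic"
               else if (props$pi > basic_min) "basic" else "neutral",
    stability = if (props$instability_index > 40) "instable" else "stable",
    hydropathy = if (props$gravy < 0) "hydrophilic" else "hydrophobic",
    has_tm = nrow(props$tm_segments) > 0L),
    class = "protein_classification")
}

#' Summarize classification counts
#'
#' @param classifications List of `protein_classification` objects.
#' @return List of named count vectors: `pi`, `stability`, `hydropathy`,
#'   `tm`, plus `total`.
#' @export
characterization_report <- function(classifications) {
  pull <- function(field) vapply(classifications, `[[`, character(1), field)
  n <- length(classifications)
  cnt <- function(x, levels) {
    out <- table(factor(x, levels = levels))
    stats::setNames(as.integer(out), levels)
  }
  pi_cls <- if (n) pull("pi_class") else character(0)
  stab <- if (n) pull("stability") else character(0)
  hyd <- if (n) pull("hydropathy") else character(0)
  tm <- if (n) vapply(classifications, `[[`, logical(1), "has_tm") else logical(0)
  list(total = n,
       pi = cnt(pi_cls, c("acidic", "neutral", "basic")),
       stability = cnt(stab, c("stable", "instable")),
       hydropathy = cnt(hyd, c("hydrophilic", "hydrophobic")),
       tm = c(with_tm = sum(tm), without_tm = sum(!tm)))
}
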