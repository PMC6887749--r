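# Independent brute-force oracles used to validate the optimized
# implementations.  These deliberately share no code with the package.

# Brute-force affine-gap local alignment score: O(n*m*(n+m)) DP that tries
# every gap-run length explicitly (gap run of length k costs open + k*ext).
brute_local_score <- function(a, b, sub, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    best <- 0
    best <- max(best, H[i, j] + sub[ca[i], cb[j]])
    if (i > 1) {
      ks <- 1:(i - 1)
      best <- max(best, max(H[i - ks + 1, j + 1] - gap_open - ks * gap_ext))
    }
    if (j > 1) {
      ks <- 1:(j - 1)
      best <- max(best, max(H[i + 1, j - ks + 1] - gap_open - ks * gap_ext))
    }
    H[i + 1, j + 1] <- best
  }
  max(H)
}

# Brute-force affine-gap global alignment score, same gap convention.
brute_global_score <- function(a, b, sub, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 1:m) H[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in 1:n) H[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (i in 1:n) for (j in 1:m) {
    best <- H[i, j] + sub[ca[i], cb[j]]
    ks <- 1:i
    best <- max(best, max(H[i - ks + 1, j + 1] - gap_open - ks * gap_ext))
    ks <- 1:j
    best <- max(best, max(H[i + 1, j - ks + 1] - gap_open - ks * gap_ext))
    H[i + 1, j + 1] <- best
  }
  H[n + 1, m + 1]
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                        collapse = "")
random_dna_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# Fine-grid isoelectric-point oracle: locate the zero of the Bjellqvist
# net-charge function by scanning a coarse grid, then a 1e-5 grid around
# the bracketing interval.  Charge model written out independently.
grid_pi_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  cnt <- function(x) sum(ch == x)
  charge <- function(pH) {
    pos <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
    neg <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
    npos <- c(1, cnt("K"), cnt("R"), cnt("H"))
    nneg <- c(1, cnt("D"), cnt("E"), cnt("C"), cnt("Y"))
    q <- 0
    for (g in seq_along(pos)) q <- q + npos[g] / (1 + 10^(pH - pos[g]))
    for (g in seq_along(neg)) q <- q - nneg[g] / (1 + 10^(neg[g] - pH))
    q
  }
  coarse <- seq(0, 14, by = 1e-3)
  qc <- vapply(coarse, charge, numeric(1))
  k <- max(which(qc > 0))
  fine <- seq(coarse[k] - 2e-3, coarse[k] + 2e-3, by = 1e-5)
  qf <- vapply(fine, charge, numeric(1))
  fine[which.min(abs(qf))]
}

# Naive per-window motif scanner with the extended consensus alphabet.
naive_motif_scan <- function(protein, consensus, max_mismatch_fraction = 0.1) {
  expand <- list(B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"), X = AA20)
  pc <- strsplit(protein, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  w <- length(cc)
  budget <- floor(w * max_mismatch_fraction)
  hits <- integer(0); mism <- integer(0)
  p <- 1L
  while (p + w - 1L <= length(pc)) {
    mm <- 0L
    for (k in seq_len(w)) {
      ok <- if (cc[k] %in% names(expand)) pc[p + k - 1L] %in% expand[[cc[k]]]
            else pc[p + k - 1L] == cc[k]
      if (!ok) mm <- mm + 1L
    }
    if (mm <= budget) {
      hits <- c(hits, p); mism <- c(mism, mm)
      p <- p + w
    } else p <- p + 1L
  }
  data.frame(start = hits, mismatches = mism)
}

# Naive overlapping IUPAC element scanner.
naive_element_scan <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  out <- integer(0)
  for (p in seq_len(max(0L, length(sc) - w + 1L))) {
    ok <- TRUE
    for (k in seq_len(w))
      if (!sc[p + k - 1L] %in% iupac[[pc[k]]]) { ok <- FALSE; break }
    if (ok) out <- c(out, p)
  }
  out
}

# Random additive distance matrix from a random tree, plus the tree.
random_additive_case <- function(ntaxa) {
  tr <- ape::unroot(ape::rtree(ntaxa))
  tr$edge.length <- round(tr$edge.length, 4) + 0.01
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Small crafted gene-model helper.
toy_model <- function(id, chrom, start, len = 300L, strand = "+",
                      n_exons = 1L) {
  bounds <- round(seq(start, start + len - 1L, length.out = 2L * n_exons))
  ex <- matrix(as.integer(bounds), ncol = 2, byrow = TRUE)
  gene_model(id, chrom, strand, start, start + len - 1L,
             exons = ex, cds = ex)
}
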