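# Distance matrices, Saitou-Nei neighbor joining, bootstrap supports, and
# reference-guided subfamily assignment.

#' Pairwise distance matrix from an alignment
#'
#' Sites with a gap in either row of a pair are excluded.  `p` is the
#' proportion of mismatching valid sites; the Poisson-corrected distance is
#' `-log(1 - p)`.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param model `"p"` (p-distance, default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal and row/column names.
#' @export
distance_matrix <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (length(alignment) < 2L) stop("need at least two aligned rows")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  n <- length(alignment)
  chars <- lapply(alignment, function(s) strsplit(s, "")[[1]])
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    valid <- a != "-" & b != "-"
    nv <- sum(valid)
    if (nv == 0L)
      stop("no gap-free sites shared by ", names(alignment)[i], " and ",
           names(alignment)[j])
    p <- sum(a[valid] != b[valid]) / nv
    val <- if (model == "p") p else {
      if (p >= 1) stop("Poisson distance undefined for p = 1 (",
                       names(alignment)[i], " vs ", names(alignment)[j], ")")
      -log(1 - p)
    }
    d[i, j] <- d[j, i] <- val
  }
  d
}

# first (row-major, i < j) minimum of the Q criterion
which_min_pair <- function(Q) {
  n <- nrow(Q)
  best <- c(1L, 2L); bv <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (Q[i, j] < bv) { bv <- Q[i, j]; best <- c(i, j) }
  }
  best
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion.  Ties are broken toward the
#' lowest label-index pair, and negative branch lengths are clamped to zero,
#' so the result is reproducible bit for bit.
#'
#' @param dm Symmetric distance matrix with row/column names (>= 3 labels).
#' @return An unrooted `phylo` object (ape).
#' @export
neighbor_joining <- function(dm) {
  if (is.null(rownames(dm))) stop("distance matrix must carry labels")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  nodes <- rownames(dm) # newick fragments of active nodes
  D <- dm
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which_min_pair(Q)
    i <- ij[1]; j <- ij[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1L, seq_along(keep)] <- D2[seq_along(keep), m - 1L] <- newdist[keep]
    D <- D2
    nodes <- c(nodes[keep], newnode)
  }
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[1], la, nodes[2], lb, nodes[3], lc)
  ape::read.tree(text = newick)
}

#' Bootstrap supports for the full-data NJ tree
#'
#' Alignment columns are resampled with replacement per replicate; the
#' support of each internal edge of the full-data tree is the percentage of
#' replicate NJ trees containing the same bipartition.  A replicate whose
#' resampled columns leave some pair without gap-free sites is redrawn, up
#' to a bounded retry budget.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the supports exactly.
#' @param model Distance model, see [distance_matrix()].
#' @return List with `tree` (full-data `phylo`, `node.label` set to integer
#'   support percentages) and `supports` (numeric vector per internal node).
#' @export
bootstrap_supports <- function(alignment, n_replicates = 100L, seed = 1L,
                               model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1L)
  full <- neighbor_joining(distance_matrix(alignment, model))
  ncols <- nchar(alignment[[1]])
  chars <- do.call(rbind, strsplit(alignment, ""))
  rownames(chars) <- names(alignment)

  reps <- vector("list", n_replicates)
  budget <- 100L * n_replicates
  set.seed(seed)
  k <- 0L
  while (k < n_replicates) {
    if (budget <= 0L) stop("bootstrap retry budget exhausted")
    budget <- budget - 1L
    cols <- sample.int(ncols, ncols, replace = TRUE)
    rows <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    dm <- tryCatch(distance_matrix(rows, model), error = function(e) NULL)
    if (is.null(dm)) next
    k <- k + 1L
    reps[[k]] <- neighbor_joining(dm)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- 100 * counts / n_replicates
  full$node.label <- as.character(round(supports))
  list(tree = full, supports = supports)
}

#' Assign subfamilies from reference leaves
#'
#' Every unlabeled leaf receives the subfamily of its nearest reference
#' leaf by patristic (path-length) distance.  Ties go to the subfamily with
#' more reference leaves, then to the lexicographically first name.
#'
#' @param tree A `phylo` object.
#' @param reference_labels Named character vector: reference leaf ->
#'   subfamily.
#' @return Named character vector mapping every leaf to a subfamily.
#' @export
assign_subfamilies <- function(tree, reference_labels) {
  if (length(reference_labels) == 0L) stop("no reference leaves given")
  refs <- names(reference_labels)
  missing <- setdiff(refs, tree$tip.label)
  if (length(missing))
    stop("reference leaf not in tree: ", paste(missing, collapse = ", "))
  pd <- ape::cophenetic.phylo(tree)
  sizes <- table(reference_labels)
  out <- stats::setNames(character(length(tree$tip.label)), tree$tip.label)
  for (leaf in tree$tip.label) {
    if (leaf %in% refs) { out[leaf] <- reference_labels[[leaf]]; next }
    dd <- pd[leaf, refs]
    cand <- unique(reference_labels[refs[dd == min(dd)]])
    if (length(cand) > 1L) {
      nref <- sizes[cand]
      cand <- cand[nref == max(nref)]
      cand <- sort(cand)[1]
    }
    out[leaf] <- cand
  }
  out
}
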