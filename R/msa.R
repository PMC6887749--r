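# In-house progressive multiple sequence alignment: k-mer guide distances,
# neighbor-joining guide tree, profile-profile merges with affine gaps.

kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  })
  tabs <- lapply(kmers, table)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ti <- tabs[[i]]; tj <- tabs[[j]]
    common <- intersect(names(ti), names(tj))
    shared <- if (length(common)) sum(pmin(ti[common], tj[common])) else 0
    denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

profile_from_seq <- function(seq, sub) {
  matrix(encode_seq(seq, sub), nrow = 1)
}

merge_profiles <- function(A, B, sub, gap_open, gap_extend) {
  res <- profile_align_cpp(A, B, sub, gap_open, gap_extend)
  take <- function(P, path) {
    out <- matrix(0L, nrow = nrow(P), ncol = length(path))
    nz <- path > 0L
    out[, nz] <- P[, path[nz], drop = FALSE]
    out
  }
  rbind(take(A, res$path_a), take(B, res$path_b))
}

# recursive post-order merge following a rooted guide tree
merge_by_guide <- function(phy, node, profiles, sub, gap_open, gap_extend) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) {
    return(list(profile = profiles[[phy$tip.label[node]]],
                rows = phy$tip.label[node]))
  }
  children <- phy$edge[phy$edge[, 1] == node, 2]
  parts <- lapply(children, merge_by_guide, phy = phy, profiles = profiles,
                  sub = sub, gap_open = gap_open, gap_extend = gap_extend)
  acc <- parts[[1]]
  for (k in seq_along(parts)[-1]) {
    acc <- list(profile = merge_profiles(acc$profile, parts[[k]]$profile,
                                         sub, gap_open, gap_extend),
                rows = c(acc$rows, parts[[k]]$rows))
  }
  acc
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively: pairwise k-mer distances feed a
#' neighbor-joining guide tree, whose post-order traversal drives
#' profile-profile global alignments with affine gaps.  De-gapping any
#' output row restores the corresponding input exactly.
#'
#' @param seqs Named character vector of sequences (length >= 1).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties.
#' @param k k-mer size for guide distances.
#' @return Named character vector of equal-length gapped rows, in input
#'   order.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(),
                            gap_open = 11, gap_extend = 1, k = 3L) {
  if (length(seqs) == 0L) stop("no sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1L) return(seqs)
  profiles <- lapply(seqs, profile_from_seq, sub = matrix)

  if (length(seqs) == 2L) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]], matrix,
                             gap_open, gap_extend)
    rows <- names(seqs)
  } else {
    gd <- kmer_distance_matrix(seqs, k = k)
    guide <- neighbor_joining(gd)
    guide <- ape::root(guide, outgroup = guide$tip.label[1],
                       resolve.root = TRUE)
    acc <- merge_by_guide(guide, length(guide$tip.label) + 1L, profiles,
                          matrix, gap_open, gap_extend)
    merged <- acc$profile
    rows <- acc$rows
  }
  letters20 <- rownames(matrix)
  out <- apply(merged, 1, function(r)
    paste(ifelse(r == 0L, "-", letters20[pmax(r, 1L)]), collapse = ""))
  stats::setNames(out, rows)[names(seqs)]
}
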