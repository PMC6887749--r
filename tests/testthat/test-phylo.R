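unit_matrix <- function(chars, match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(chars), length(chars),
              dimnames = list(chars, chars))
  diag(m) <- match
  m
}

test_that("progressive MSA handles identical and near-identical inputs", {
  aln <- progressive_msa(c(a = "ACDEF", b = "ACDEF"))
  expect_identical(unname(aln), c("ACDEF", "ACDEF"))

  m <- unit_matrix(c("A", "C", "D", "E"))
  aln2 <- progressive_msa(c(r1 = "ACDE", r2 = "ACE"),
                          matrix = m, gap_open = 0, gap_extend = 2)
  expect_identical(nchar(aln2[["r1"]]), 4L)
  expect_identical(aln2[["r1"]], "ACDE")
  expect_identical(lengths(regmatches(aln2[["r2"]],
                                      gregexpr("-", aln2[["r2"]]))), 1L)
})

test_that("de-gapping MSA rows restores every input sequence", {
  set.seed(21)
  base <- random_protein_seq(120)
  seqs <- setNames(c(base, vapply(1:5, function(i)
    mutate_protein(base, 0.7, seed = i), character(1))), paste0("t", 0:5))
  aln <- progressive_msa(seqs)
  expect_identical(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln), seqs)
})

test_that("distance models follow their formulas and reject empty overlap", {
  aln <- c(x = "AAAA", y = "AAAT")
  expect_equal(distance_matrix(aln, "p")["x", "y"], 0.25)
  expect_equal(distance_matrix(aln, "poisson")["x", "y"], -log(0.75))
  expect_equal(distance_matrix(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_error(distance_matrix(c(x = "AA--", y = "--AA")), "gap-free")
  # Poisson correction never shrinks a distance
  set.seed(22)
  base <- random_protein_seq(60)
  seqs <- setNames(c(base, vapply(1:3, function(i)
    mutate_protein(base, 0.5, seed = 100 + i), character(1))),
    paste0("s", 1:4))
  aln2 <- progressive_msa(seqs)
  expect_true(all(distance_matrix(aln2, "poisson") >=
                    distance_matrix(aln2, "p") - 1e-12))
})

test_that("NJ reproduces a hand-built additive four-taxon matrix exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) gives AB=3 AC=5 AD=6 BC=6 BD=7 CD=7
  lab <- c("A", "B", "C", "D")
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- neighbor_joining(dm)
  pl <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(pl, dm, tolerance = 1e-12)
  # AB|CD split: A and B form a cherry
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # leaf branch lengths are 1,2,3,4; internal edge 1
  expect_setequal(round(tr$edge.length, 9), c(1, 2, 3, 4, 1))
})

test_that("NJ recovers random additive matrices up to 8 taxa exactly", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (case in 1:50) {
    case_data <- random_additive_case(sample(4:8, 1))
    tr <- neighbor_joining(case_data$dm)
    pl <- ape::cophenetic.phylo(tr)[rownames(case_data$dm),
                                    colnames(case_data$dm)]
    expect_lt(max(abs(pl - case_data$dm)), 1e-9)
    expect_equal(phangorn::RF.dist(tr, case_data$tree), 0)
    # cross-check topology against the reference NJ implementation
    expect_equal(phangorn::RF.dist(tr, ape::nj(case_data$dm)), 0)
  }
})

test_that("NJ input validation", {
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(dm), "at least 3")
})

test_that("three taxa give the unique star resolution", {
  lab <- c("A", "B", "C")
  dm <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3, dimnames = list(lab, lab))
  tr <- neighbor_joining(dm)
  expect_identical(ape::Ntip(tr), 3L)
  pl <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(pl, dm, tolerance = 1e-12)
})

test_that("bootstrap supports are deterministic and sensible", {
  set.seed(24)
  # two clearly separated 4-taxon groups with 20 diagnostic columns
  g1 <- strrep("A", 20); g2 <- strrep("W", 20)
  noise <- function() random_protein_seq(30)
  aln <- setNames(
    vapply(1:8, function(i) {
      core <- if (i <= 4) g1 else g2
      paste0(core, substr(noise(), 1, 10)) }, character(1)),
    paste0("t", 1:8))
  # equalize: rows already equal length (30)
  bs <- bootstrap_supports(aln, n_replicates = 100, seed = 5)
  # the internal edge separating the two groups must be near-certain
  expect_true(any(bs$supports >= 95))

  bs2 <- bootstrap_supports(aln, n_replicates = 100, seed = 5)
  expect_identical(bs$supports, bs2$supports)

  bs1 <- bootstrap_supports(aln, n_replicates = 1, seed = 9)
  expect_true(all(bs1$supports %in% c(0, 100)))
})

test_that("subfamily assignment follows nearest reference with tie rules", {
  aln <- c(ref1 = "AAAAAAAAAA", ref2 = "WWWWWWWWWW",
           u1 = "AAAAAAAAAW", u2 = "WWWWWWWWWA", extra = "AAAAAWWWWW")
  tr <- neighbor_joining(distance_matrix(aln))
  out <- assign_subfamilies(tr, c(ref1 = "SubA", ref2 = "SubB"))
  expect_identical(unname(out["u1"]), "SubA")
  expect_identical(unname(out["u2"]), "SubB")
  # all leaves referenced: identity
  all_ref <- setNames(c("X", "Y", "Z", "W", "V"), names(aln))
  expect_identical(assign_subfamilies(tr, all_ref)[names(aln)], all_ref)
  expect_error(assign_subfamilies(tr, character(0)), "no reference")
})
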