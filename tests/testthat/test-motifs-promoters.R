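motif_df <- function(ids, cons) data.frame(motif_id = ids, consensus = cons,
                                           stringsAsFactors = FALSE)

test_that("extended-alphabet letters match their residue sets", {
  # J matches I; full window identical otherwise
  motifs <- motif_df("13", "ALJLGLLWWQSDSNN")
  prot <- paste0("MKKK", "ALILGLLWWQSDSNN", "KKK")
  hits <- scan_protein_motifs(prot, motifs)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 5L)
  expect_identical(hits$mismatches, 0L)
  # B = {N,D}, Z = {Q,E}, X = anything
  m2 <- motif_df("bzx", "BZXBZX")
  expect_identical(nrow(scan_protein_motifs("NEWDQC", m2,
                                            max_mismatch_fraction = 0)), 1L)
  expect_identical(nrow(scan_protein_motifs("WEWDQC", m2,
                                            max_mismatch_fraction = 0)), 0L)
})

test_that("no hits on a motif-free protein or when motif exceeds length", {
  tab <- read_motif_table(system.file("extdata", "abcg_motif_table.tsv",
                                      package = "famsurvey"))
  expect_identical(nrow(scan_protein_motifs(strrep("G", 300), tab)), 0L)
  expect_identical(nrow(scan_protein_motifs("ACD", tab)), 0L)
})

test_that("scanner equals the naive per-window oracle on random proteins", {
  tab <- read_motif_table(system.file("extdata", "abcg_motif_table.tsv",
                                      package = "famsurvey"))
  motifs <- tab[tab$motif_id %in% c("1", "7", "13", "19"), ]
  set.seed(41)
  for (case in 1:100) {
    prot <- random_protein_seq(300)
    # plant one noisy motif instance to make hits likely
    inst <- strsplit(motifs$consensus[sample.int(nrow(motifs), 1)], "")[[1]]
    inst[inst %in% c("B", "Z", "J", "X")] <- "A"
    at <- sample.int(300 - length(inst), 1)
    substr(prot, at, at + length(inst) - 1L) <- paste(inst, collapse = "")
    got <- scan_protein_motifs(prot, motifs)
    for (r in seq_len(nrow(motifs))) {
      want <- naive_motif_scan(prot, motifs$consensus[r])
      g <- got[got$motif_id == motifs$motif_id[r], ]
      expect_identical(g$start, want$start)
      expect_identical(g$mismatches, want$mismatches)
    }
  }
})

test_that("motif width statistics match the bundled consensus table", {
  tab <- read_motif_table(system.file("extdata", "abcg_motif_table.tsv",
                                      package = "famsurvey"))
  st <- motif_width_stats(tab)
  expect_identical(st, list(count = 20L, min_width = 15L, max_width = 50L))
  one <- motif_width_stats(tab[tab$motif_id == "1", ])
  expect_identical(one, list(count = 1L, min_width = 41L, max_width = 41L))
  expect_identical(motif_width_stats(motif_df(c("a", "b"),
                                              c(strrep("A", 6), strrep("C", 200)))),
                   list(count = 2L, min_width = 6L, max_width = 200L))
  expect_error(motif_width_stats(motif_df(character(0), character(0))),
               "empty")
})

test_that("promoter extraction follows strand conventions and truncation", {
  chrom <- random_dna_seq(8000)
  genome <- c(chr1 = chrom)
  plus <- gene_model("p", "chr1", "+", 2951, 4000,
                     exons = matrix(c(2951, 4000), ncol = 2),
                     cds = matrix(c(3001, 4000), ncol = 2))
  pr <- extract_promoter(genome, plus)
  expect_identical(pr$sequence, substr(chrom, 1001, 3000))
  expect_identical(pr$length, 2000L)
  expect_false(pr$truncated)

  minus <- gene_model("m", "chr1", "-", 4000, 5050,
                      exons = matrix(c(4000, 5050), ncol = 2),
                      cds = matrix(c(4000, 5000), ncol = 2))
  pm <- extract_promoter(genome, minus)
  expect_identical(pm$sequence, famsurvey:::revcomp(substr(chrom, 5001, 7000)))

  early <- gene_model("e", "chr1", "+", 100, 700,
                      exons = matrix(c(100, 700), ncol = 2),
                      cds = matrix(c(150, 700), ncol = 2))
  pe <- extract_promoter(genome, early)
  expect_identical(pe$length, 149L)
  expect_true(pe$truncated)

  nocds <- plus; nocds$cds <- matrix(integer(0), ncol = 2)
  expect_error(extract_promoter(genome, nocds), "no CDS")
})

test_that("promoter extraction is invariant under strand mirroring", {
  set.seed(42)
  chrom <- random_dna_seq(6000)
  model <- gene_model("g", "chr1", "+", 3001, 3600,
                      exons = matrix(c(3001, 3600), ncol = 2),
                      cds = matrix(c(3001, 3600), ncol = 2))
  pr <- extract_promoter(c(chr1 = chrom), model)
  flipped_chrom <- famsurvey:::revcomp(chrom)
  L <- nchar(chrom)
  flipped <- gene_model("g", "chr1", "-", L - 3600 + 1, L - 3001 + 1,
                        exons = matrix(c(L - 3600 + 1, L - 3001 + 1), ncol = 2),
                        cds = matrix(c(L - 3600 + 1, L - 3001 + 1), ncol = 2))
  pf <- extract_promoter(c(chr1 = flipped_chrom), flipped)
  expect_identical(pf$sequence, pr$sequence)
})

test_that("cis-element scanning counts overlapping sense-strand hits", {
  dict <- read_cis_elements(system.file("extdata", "cis_elements.tsv",
                                        package = "famsurvey"))
  pr <- scan_cis_elements("GAACCGTCTTGACATGT", dict)
  expect_identical(unname(pr$element_counts["W-box"]), 1L)
  expect_identical(pr$hit_positions[["W-box"]], 9L)
  # the mutated variant has no W-box
  pr2 <- scan_cis_elements("GAACCGTCTTCACATGT", dict)
  expect_identical(unname(pr2$element_counts["W-box"]), 0L)
  # overlapping occurrences are all counted
  d2 <- data.frame(name = "poly", pattern = "AA", category = "other")
  pr3 <- scan_cis_elements("AAAA", d2)
  expect_identical(pr3$hit_positions[["poly"]], c(1L, 2L, 3L))
})

test_that("cis scanner equals the naive oracle including IUPAC degeneracy", {
  pats <- c("TTGAC", "ACGTGGC", "WTTGACY", "RYSWKM")
  set.seed(43)
  for (case in 1:50) {
    s <- random_dna_seq(500)
    for (p in pats) {
      d <- data.frame(name = "x", pattern = p, category = "other")
      expect_identical(scan_cis_elements(s, d)$hit_positions[["x"]],
                       naive_element_scan(s, p), info = p)
    }
  }
})

test_that("allele comparison reports deletions and lost elements", {
  dict <- read_cis_elements(system.file("extdata", "cis_elements.tsv",
                                        package = "famsurvey"))
  set.seed(44)
  # A/C-only background: the planted 17-mer is then the unique G/T-bearing
  # region, so the alignment places the deletion run unambiguously
  base <- paste(sample(c("A", "C"), 2000, replace = TRUE), collapse = "")
  seg <- "GAACCGTCTTGACATGT" # 17 bp, carries one W-box
  rob <- paste0(substr(base, 1, 798), seg, substr(base, 816, 2000))
  m9 <- paste0(substr(rob, 1, 798), substring(rob, 816)) # 17 bp excised

  vc <- compare_promoter_alleles(rob, m9, dict)
  expect_identical(nrow(vc$deletion_segments), 1L)
  expect_identical(vc$deletion_segments$length, 17L)
  expect_identical(vc$deletion_segments$sequence, seg)
  expect_identical(vc$deletion_segments$offset, 799L)
  expect_gte(unname(vc$lost_elements["W-box"]), 1L)

  # identical alleles: nothing lost, nothing gained
  same <- compare_promoter_alleles(rob, rob, dict)
  expect_identical(nrow(same$deletion_segments), 0L)
  expect_identical(length(same$lost_elements), 0L)

  # point substitution destroying the W-box: no deletion, one lost element
  a2 <- sub("TTGAC", "TTCAC", rob, fixed = TRUE)
  vs <- compare_promoter_alleles(rob, a2, dict)
  expect_identical(nrow(vs$deletion_segments), 0L)
  expect_identical(unname(vs$lost_elements["W-box"]), 1L)

  # anti-symmetry: swapping alleles swaps lost and gained
  rev <- compare_promoter_alleles(m9, rob, dict)
  expect_identical(rev$gained_elements, vc$lost_elements)
  expect_identical(rev$lost_elements, vc$gained_elements)

  expect_error(compare_promoter_alleles(strrep("A", 300), strrep("C", 300),
                                        dict),
               "identity")
})
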