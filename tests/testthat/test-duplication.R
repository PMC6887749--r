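test_that("exon/intron statistics follow the single-transcript model", {
  one <- toy_model("g1", "chr1", 100L, n_exons = 1L)
  st <- gene_structure_stats(one)
  expect_identical(st, list(exon_count = 1L, intron_count = 0L,
                            intronless = TRUE))
  four <- toy_model("g2", "chr1", 100L, len = 600L, n_exons = 4L)
  st4 <- gene_structure_stats(four)
  expect_identical(st4$exon_count, 4L)
  expect_identical(st4$intron_count, 3L)
  expect_false(st4$intronless)
})

make_ranked_models <- function(ids, chrom = "chr1", gap = 1000L) {
  models <- list()
  for (k in seq_along(ids))
    models[[ids[k]]] <- toy_model(ids[k], chrom, k * gap)
  f <- tempfile(fileext = ".gff3")
  write_gff3(models, f)
  read_gff3(f)
}

test_that("tandem rule: same chromosome, at most one intervening gene", {
  set.seed(31)
  prot <- random_protein_seq(120)
  sim <- mutate_protein(prot, 0.85, seed = 2)
  far <- random_protein_seq(120)

  # adjacent members at 85% identity
  models <- make_ranked_models(c("m1", "m2"))
  tan <- detect_tandem(c("m1", "m2"), models,
                       c(m1 = prot, m2 = sim), min_identity_pct = 70)
  expect_identical(nrow(tan), 1L)
  expect_identical(tan$intervening, 0L)
  expect_identical(tan$gene_a, "m1")

  # one intervening decoy still qualifies
  models3 <- make_ranked_models(c("m1", "d1", "m2"))
  tan3 <- detect_tandem(c("m1", "m2"), models3,
                        c(m1 = prot, m2 = sim), min_identity_pct = 70)
  expect_identical(nrow(tan3), 1L)
  expect_identical(tan3$intervening, 1L)

  # two intervening decoys disqualify
  models4 <- make_ranked_models(c("m1", "d1", "d2", "m2"))
  expect_identical(nrow(detect_tandem(c("m1", "m2"), models4,
                                      c(m1 = prot, m2 = sim), 70)), 0L)

  # different chromosomes disqualify
  f <- tempfile(fileext = ".gff3")
  write_gff3(list(toy_model("m1", "chr1", 1000L),
                  toy_model("m2", "chr2", 2000L)), f)
  expect_identical(nrow(detect_tandem(c("m1", "m2"), read_gff3(f),
                                      c(m1 = prot, m2 = sim), 70)), 0L)

  # adjacency without homology disqualifies
  expect_identical(nrow(detect_tandem(c("m1", "m2"), models,
                                      c(m1 = prot, m2 = far), 70)), 0L)
})

test_that("segmental rule: strict >80% identity, mutual coverage, not tandem", {
  f <- tempfile(fileext = ".gff3")
  write_gff3(list(toy_model("s1", "chr1", 1000L),
                  toy_model("s2", "chr2", 1000L),
                  toy_model("s3", "chr3", 1000L)), f)
  models <- read_gff3(f)

  # hand-built pair at exactly 80.0% identity: 8/10 positions match and
  # global alignment has no incentive to gap (same lengths, affine costs)
  a <- "AAAAAAAAAA"
  b <- "AAAAAAAAWW"
  seg <- detect_segmental(c("s1", "s2"), models, c(s1 = a, s2 = b),
                          min_identity_pct = 80)
  expect_identical(nrow(seg), 0L) # 80.0 is not > 80

  b2 <- "AAAAAAAAAW" # 90%
  seg2 <- detect_segmental(c("s1", "s2"), models, c(s1 = a, s2 = b2),
                           min_identity_pct = 80)
  expect_identical(nrow(seg2), 1L)
  expect_identical(seg2$mode, "segmental")
  expect_identical(seg2$chrom_a, "chr1")
  expect_identical(seg2$chrom_b, "chr2")

  # a pair already classified tandem is excluded
  tan <- data.frame(gene_a = "s1", gene_b = "s2")
  expect_identical(nrow(detect_segmental(c("s1", "s2"), models,
                                         c(s1 = a, s2 = b2), tandem = tan)), 0L)

  # raising the threshold never adds pairs
  set.seed(32)
  prots <- c(s1 = random_protein_seq(100), s3 = random_protein_seq(100))
  prots["s2"] <- mutate_protein(prots[["s1"]], 0.9, seed = 3)
  lo <- detect_segmental(names(prots), models, prots, min_identity_pct = 70)
  hi <- detect_segmental(names(prots), models, prots, min_identity_pct = 85)
  expect_true(all(paste(hi$gene_a, hi$gene_b) %in% paste(lo$gene_a, lo$gene_b)))
})

test_that("localization table groups by chromosome and sorts by start", {
  f <- tempfile(fileext = ".gff3")
  write_gff3(list(toy_model("g1", "chr2", 500L),
                  toy_model("g2", "chr1", 900L),
                  toy_model("g3", "chr1", 100L)), f)
  models <- read_gff3(f)
  tab <- chromosome_map(c("g1", "g2", "g3"), models,
                        c(g1 = "F3", g2 = "F2", g3 = "F1"))
  expect_identical(tab$gene_id, c("g3", "g2", "g1"))
  expect_identical(tab$family_name, c("F1", "F2", "F3"))
  expect_identical(nrow(chromosome_map(character(0), models)), 0L)
})
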