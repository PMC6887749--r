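# The generator is first-class code: these tests check its contracts
# directly (determinism, geometry, translation consistency), independent of
# the analysis modules that consume its output.

small_config <- function(...) {
  synthetic_config(n_chromosomes = 2L, chromosome_length = 60000L,
                   n_family_genes = 6L, n_decoy_genes = 4L,
                   n_tandem_clusters = 1L, n_segmental_pairs = 1L, ...)
}

test_that("mutate_protein hits the identity target position-wise", {
  set.seed(51)
  s <- random_protein_seq(200)
  out <- mutate_protein(s, 0.85, seed = 7)
  expect_identical(nchar(out), 200L)
  ident <- mean(strsplit(s, "")[[1]] == strsplit(out, "")[[1]])
  expect_gte(ident, 0.83); expect_lte(ident, 0.87)

  # different seeds differ but land in the same band
  out2 <- mutate_protein(s, 0.85, seed = 8)
  expect_false(identical(out, out2))
  ident2 <- mean(strsplit(s, "")[[1]] == strsplit(out2, "")[[1]])
  expect_equal(ident2, ident)

  expect_identical(mutate_protein(s, 1.0, seed = 1), s)
  expect_error(mutate_protein(s, 0, seed = 1), "target_identity")
  expect_error(mutate_protein("", 0.9, seed = 1), "non-empty")
})

test_that("the same config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_survey_dataset(small_config(), dir = d1)
  generate_survey_dataset(small_config(), dir = d2)
  for (f in c("genome.fasta", "annotation.gff3", "proteome.fasta",
              "queries.fasta", "truth_family_members.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  generate_survey_dataset(small_config(rng_seed = 999L), dir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d3, "genome.fasta"))))
})

test_that("an empty family yields a decoy-only dataset", {
  cfg <- synthetic_config(n_family_genes = 0L, n_tandem_clusters = 0L,
                          n_segmental_pairs = 0L, n_decoy_genes = 3L,
                          n_chromosomes = 1L, chromosome_length = 20000L)
  ds <- generate_survey_dataset(cfg, dir = withr::local_tempdir())
  expect_identical(length(ds$truth$family_members), 0L)
  expect_identical(length(ds$proteome), 3L)
  expect_true(all(startsWith(names(ds$proteome), "dec")))
})

test_that("tandem geometry recounted from the emitted GFF3 is exact", {
  cfg <- synthetic_config(n_tandem_clusters = 3L, intervening_per_cluster = 1L,
                          n_family_genes = 12L, n_decoy_genes = 8L)
  ds <- generate_survey_dataset(cfg, dir = withr::local_tempdir())
  models <- read_gff3(ds$paths$gff3)
  for (k in seq_len(nrow(ds$truth$tandem_pairs))) {
    a <- models[[ds$truth$tandem_pairs$gene_a[k]]]
    b <- models[[ds$truth$tandem_pairs$gene_b[k]]]
    expect_identical(a$chromosome, b$chromosome)
    # exactly one decoy between the pair in annotation order
    expect_identical(abs(a$rank - b$rank), 2L)
  }
  # zero intervening genes when requested
  cfg0 <- synthetic_config(n_tandem_clusters = 2L,
                           intervening_per_cluster = 0L)
  ds0 <- generate_survey_dataset(cfg0, dir = withr::local_tempdir())
  models0 <- read_gff3(ds0$paths$gff3)
  for (k in seq_len(nrow(ds0$truth$tandem_pairs))) {
    a <- models0[[ds0$truth$tandem_pairs$gene_a[k]]]
    b <- models0[[ds0$truth$tandem_pairs$gene_b[k]]]
    expect_identical(abs(a$rank - b$rank), 1L)
  }
})

test_that("segmental pairs sit on different chromosomes at the set identity", {
  ds <- generate_survey_dataset(small_config(segmental_identity = 0.85),
                                dir = withr::local_tempdir())
  models <- read_gff3(ds$paths$gff3)
  for (k in seq_len(nrow(ds$truth$segmental_pairs))) {
    a <- ds$truth$segmental_pairs$gene_a[k]
    b <- ds$truth$segmental_pairs$gene_b[k]
    expect_false(models[[a]]$chromosome == models[[b]]$chromosome)
    ident <- mean(strsplit(ds$proteome[[a]], "")[[1]] ==
                    strsplit(ds$proteome[[b]], "")[[1]])
    expect_gte(ident, 0.83); expect_lte(ident, 0.87)
  }
})

test_that("emitted proteome equals the translation of the emitted CDS", {
  ds <- generate_survey_dataset(small_config(), dir = withr::local_tempdir())
  models <- read_gff3(ds$paths$gff3)
  genome <- read_fasta(ds$paths$genome)
  for (m in models) {
    cds <- paste(substring(genome[[m$chromosome]], m$cds[, 1], m$cds[, 2]),
                 collapse = "")
    if (m$strand == "-") cds <- famsurvey:::revcomp(cds)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(aa, paste0(ds$proteome[[m$gene_id]], "*"))
  }
})

test_that("infeasible sizing is rejected with the violated budget named", {
  cfg <- synthetic_config(n_chromosomes = 1L, chromosome_length = 9000L,
                          n_family_genes = 6L, n_decoy_genes = 4L,
                          n_tandem_clusters = 1L, n_segmental_pairs = 0L)
  expect_error(generate_survey_dataset(cfg, dir = withr::local_tempdir()),
               "chromosome_length")
  expect_error(synthetic_config(segmental_identity = 0.8), "0.8")
  expect_error(synthetic_config(n_family_genes = 2L, n_tandem_clusters = 2L),
               "at least")
})
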