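# famsurvey

A desk-scale, fully offline R implementation of the genome-wide
gene-family survey workflow, modelled on surveys of the plant ATP-binding
cassette (ABC) transporter superfamily. Given an annotated genome (FASTA +
GFF3), a proteome, and seed query proteins, the package:

* **identifies family members** — exact Smith–Waterman screening (affine
  gaps, BLOSUM62, gap open 11 / extend 1; thresholds 30% identity, 0.5
  query coverage) followed by confirmation of the nucleotide-binding-domain
  motif triplet: Walker A `[AG]x(4)GK[ST]`, ABC signature `LSGGQ` (≤1
  mismatch), Walker B `[ILVFMA]{4}DE`, required in N→C order;
* **characterizes proteins** ProtParam-style — average molecular weight,
  isoelectric point (Bjellqvist pKa set, bisection to |q| < 1e-4),
  charged-residue counts, elemental formula, Guruprasad instability index
  (instable when > 40), aliphatic index, Kyte–Doolittle GRAVY, and a
  transparent hydropathy-window transmembrane caller (window 19, cutoff
  1.6);
* **builds phylogenies** — in-house progressive MSA, p-distance or Poisson
  distances, Saitou–Nei neighbor joining with deterministic tie-breaking
  and zero-clamped branch lengths, column-bootstrap supports, and
  reference-guided subfamily assignment;
* **classifies duplications** — tandem pairs (same chromosome, ≤ 1
  intervening annotated gene, ≥ 70% global identity) and segmental pairs
  (> 80% identity strictly, mutual coverage ≥ 0.5, disjoint from tandem);
* **scans motifs and promoters** — extended-alphabet consensus motifs
  (B/Z/J/X), 2 kb promoters upstream of the translation start site,
  overlapping sense-strand cis-element counts, and promoter allele
  comparison that reports deletion segments and lost/gained elements
  (e.g. W-box loss);
* **summarizes expression** — 2^−ΔΔCt fold changes, log2 fold-change
  matrices, and inclusive 2-fold induction calls;
* **generates synthetic genomes with planted truth** so that all of the
  above is testable without downloading genome assemblies.

See `vignettes/gene-family-survey.Rmd` for the full methods account.

## Worked example

Generate a synthetic annotated genome and run the whole survey on it:

```r
library(famsurvey)

ds  <- generate_survey_dataset(synthetic_config(), dir = "synth")
cfg <- list(genome = ds$paths$genome, gff3 = ds$paths$gff3,
            proteome = ds$paths$proteome, queries = ds$paths$queries,
            motif_table = system.file("extdata", "abcg_motif_table.tsv",
                                      package = "famsurvey"),
            element_dictionary = system.file("extdata", "cis_elements.tsv",
                                            package = "famsurvey"))
report <- run_survey(cfg, out_dir = "survey_out")
str(report[c("n_members", "intronless_count", "tandem_pair_count",
             "segmental_pair_count", "subfamily_sizes", "motif_stats")])
#> List of 6
#>  $ n_members           : int 12
#>  $ intronless_count    : int 3
#>  $ tandem_pair_count   : int 2
#>  $ segmental_pair_count: int 2
#>  $ subfamily_sizes     :List of 2
#>   ..$ SynA: int 10
#>   ..$ SynG: int 2
#>  $ motif_stats         :List of 3
#>   ..$ count    : int 20
#>   ..$ min_width: int 15
#>   ..$ max_width: int 50
```

All 12 planted family genes are recovered (the 8 motif-free decoys are
rejected), both planted tandem clusters and both cross-chromosome
segmental pairs are classified correctly, the intronless set matches the
generator's record, and the bundled consensus motif table contains 20
motifs spanning widths 15–50. `survey_out/` holds the characterization
table, duplication pairs, localization map, newick tree with bootstrap
supports, promoter element matrix, and a manifest of every parameter in
effect; rerunning with the same config reproduces the report byte for
byte.

Single stages are plain functions — for example, comparing two promoter
alleles that differ by a 17 bp deletion carrying a W-box:

```r
dict <- read_cis_elements(system.file("extdata", "cis_elements.tsv",
                                      package = "famsurvey"))
vc <- compare_promoter_alleles(reference_allele, deletion_allele, dict)
vc$deletion_segments   # sequence / length / offset of each gap run
vc$lost_elements       # e.g. W-box: 1
```

A thin CLI lives at `inst/scripts/famsurvey.R`
(`Rscript famsurvey.R simulate --out DIR`, `Rscript famsurvey.R all
--config survey.yaml --out DIR`).

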