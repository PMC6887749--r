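---
title: "Methods: a desk-scale genome-wide gene-family survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale genome-wide gene-family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsurvey)
```

## What this package models

famsurvey re-implements, as reusable and tested code, the standard workflow
of a genome-wide gene-family survey as practised for the plant ATP-binding
cassette (ABC) transporter superfamily: starting from an annotated genome
(FASTA + GFF3), a proteome, and a set of seed query proteins, it identifies
family members, characterizes and classifies their proteins, builds a
neighbor-joining phylogeny with bootstrap supports, classifies tandem and
segmental duplications, scans protein motifs and promoter cis-elements,
compares promoter alleles, and summarizes hormone-induction expression.

The real surveys of this kind run on downloaded genome assemblies. Those
downloads, and several thresholds the original analyses leave unstated, are
out of scope here; instead the package ships a synthetic-genome generator
with planted ground truth, so that every stage of the pipeline can be
exercised and verified offline.

## Member identification

BLASTp-style screening is replaced by an exact Smith–Waterman local
aligner with affine gaps (Gotoh's three-state DP, compiled): at desk scale
there is no need for seeded heuristics, and an exact aligner can be checked
against a brute-force oracle. A gap run of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{ext}$ (BLAST convention; defaults BLOSUM62,
open 11, extend 1). A subject passes the screen when **any** query reaches
both thresholds — 30% identity over alignment columns and 0.5 query
coverage by default. The original surveys do not state their BLASTp
acceptance criterion, so these thresholds are explicit configuration, not a
reconstruction.

Candidates are then confirmed by the nucleotide-binding-domain (NBD) motif
triplet that defines the family, searched left to right:

* Walker A: `[AG]-x(4)-G-K-[ST]` (exact),
* ABC signature: `LSGGQ` with at most one mismatch (the signature is the
  best-known degenerate of the three),
* Walker B: four hydrophobic residues from `{I,L,V,F,M,A}` followed by
  `DE` (exact).

`confirmed` requires all three in N-to-C order. This ordered-consensus
check captures the essence of the Pfam ABC-transporter domain (PF00005)
without a profile HMM; a user-supplied PSSM can replace it where finer
discrimination is needed. Members are named by chromosomal position
(natural chromosome order, so chr2 precedes chr10, then start coordinate).

## Protein characterization

`compute_properties()` reproduces the ProtParam-style record:

* molecular weight: sum of average residue masses plus one water;
* isoelectric point: the unique zero of the Bjellqvist net-charge function
  (N-terminus 7.5, C-terminus 3.55; side chains C 9.0, D 4.05, E 4.45,
  H 5.98, K 10.0, R 12.0, Y 10.0), found by bisection on pH 0–14 to
  $|q| < 10^{-4}$ — the charge is strictly decreasing in pH, so the root is
  unique and bisection cannot fail;
* instability index: $(10/L)\sum_i \mathrm{DIWV}(x_i, x_{i+1})$ with the
  Guruprasad dipeptide weights (shipped as plain text); a protein is called
  *instable* only when the index is strictly above 40;
* aliphatic index: $X_A + 2.9\,X_V + 3.9\,(X_I + X_L)$ in mole percent;
* GRAVY: the mean Kyte–Doolittle hydropathy; *hydrophilic* means strictly
  negative.

pI class boundaries (acidic < 6.5, basic > 7.5) are configurable; the
bands behind published acidic/neutral/basic splits are generally not
reported, so no attempt is made to reproduce any specific split.

Transmembrane segments are called by a transparent Kyte–Doolittle sliding
window (width 19, mean-hydropathy cutoff 1.6, overlapping windows merged).
This is a deliberate, clearly-labelled stand-in for HMM-based predictors:
it finds unambiguous hydrophobic cores and is fully auditable, but it is
not a reproduction of TMHMM and will disagree with it near marginal
helices.

## Phylogeny

The multiple alignment is an in-house progressive aligner: 3-mer
fractional-common-k-mer distances feed a neighbor-joining guide tree whose
post-order traversal drives profile–profile global alignments (column
score = mean pairwise substitution score, gap-vs-residue scoring 0, affine
gap penalties as above). Fidelity to any particular MSA heuristic is not a
goal; determinism, auditability, and the round-trip guarantee (de-gapping
any row restores its input) are.

Distances default to the p-distance (pairwise deletion of gapped sites);
a Poisson correction $-\ln(1-p)$ is available by flag. Neighbor joining is
the Saitou–Nei agglomeration on the Q criterion with two reproducibility
rules: ties are broken toward the first (lowest-index) pair, and negative
branch lengths are clamped to zero. On additive matrices the algorithm is
exact — the test suite checks that path lengths reproduce random additive
matrices to 1e-9 and that topologies match an independent NJ
implementation.

Bootstrap resamples alignment columns with replacement; support of an
internal edge is the percentage of replicate trees containing the same
bipartition (counted with `ape::prop.clades`). A replicate that leaves some
pair with no gap-free sites is redrawn, within a bounded retry budget, so a
fixed seed always yields the same supports. Subfamilies are assigned to
unlabeled leaves from the nearest reference leaf by patristic distance,
with ties resolved toward the larger reference set, then lexicographically.

## Duplication classification

Two genes form a **tandem** pair when they lie on the same chromosome with
at most one intervening gene — counted over *all* annotated genes, the
stricter reading — and their proteins reach 70% global-alignment identity.
The homology cutoff for "adjacent homologous gene" is not stated in the
surveys this models; 70% is permissive enough that genuinely tandem pairs
(which share coding lengths and motif arrays) qualify, and it is
configurable. A **segmental** pair needs identity *strictly* above 80%
(the published rule), mutual coverage of at least 0.5 in a global
alignment (so short domain-only matches cannot qualify), and must not
already be tandem — the two sets are disjoint by construction. Whether the
published ">80%" meant local or full-length identity is unknowable from
the text; this package documents its global-alignment choice rather than
guessing.

## Motifs, promoters, and allele comparison

Protein motifs are mismatch-tolerant consensus strings over the extended
alphabet B = {N,D}, Z = {Q,E}, J = {I,L}, X = any — the alphabet used by
published MEME consensus tables. A window matches when its mismatches stay
within `floor(width * 0.1)`; per motif, hits are taken leftmost-greedy and
non-overlapping (MEME-site style). Promoter cis-elements, by contrast, are
counted at *every* overlapping position (PlantCARE style); the asymmetry is
intentional. Element scanning is sense-strand only by default, matching how
such element counts are conventionally reported; a both-strands flag
exists.

Promoters are the 2 kb immediately upstream of the **translation** start
site (the first CDS base), not the transcription start, on the gene's
sense strand; promoters are truncated, with a flag, at contig edges.

`compare_promoter_alleles()` globally aligns two alleles (nucleotide
match +2 / mismatch −3, gap open 10 / extend 0.5), reports contiguous gap
runs as deletion segments (sequence, length, offset in the reference
allele), and diffs the element scans of the two alleles into lost and
gained counts, so a deletion that removes a W-box and a point substitution
that destroys one are both detected. Comparisons below 50% alignment
identity are refused — such sequences are not alleles of one promoter.
Note that when a deletion sits in locally repetitive context, equal-scoring
alignments can shift the gap run by a few bases; the deleted *length* is
stable, the reported segment is one of the equivalent placements.

## Expression summaries

Relative expression follows $2^{-\Delta\Delta C_t}$ from raw cycle
thresholds against an internal reference gene; log2 fold-change matrices
use a configurable pseudocount (0 for qPCR-derived values). A gene is
called *induced* when any timepoint reaches 2-fold (inclusive). The 2-fold
threshold operationalizes the qualitative "strongly induced" of survey
prose and is labelled artifact policy, configurable everywhere it is used.

## The synthetic genome and what passing tests mean

`generate_survey_dataset()` emulates the features the pipeline must
detect: multi-chromosome genomes whose family genes carry the NBD triplet
(planted motif windows are protected from mutation), motif-free decoys,
tandem clusters with 0 or 1 intervening decoy, cross-chromosome segmental
pairs at a configured identity (default 0.85, strictly above the 0.8
rule), a configurable intronless fraction, and promoter elements planted
at recorded non-overlapping sense-strand offsets into background that has
been scrubbed of accidental dictionary matches. Defaults: 3 chromosomes of
120 kb, 12 family genes (2 tandem clusters, 2 segmental pairs), 8 decoys,
intronless fraction 0.25. Non-duplicated family genes sit at 60–70%
identity to one of two subfamily prototypes so that no *unplanted* pair
crosses the segmental threshold; the prototypes double as seed queries and
as phylogeny reference leaves.

Genes are single-transcript, standard genetic code, ATG start, with
introns (GT..AG) inserted only between complete codons, so the emitted
proteome is exactly the translation of the emitted CDS. Everything derives
from one integer seed; the same configuration is byte-identical across
runs. Mutations are substitutions only, so pairwise identity is
position-wise and threshold tests are unambiguous.

What the generator does **not** emulate: indels and codon bias, realistic
intergenic composition, overlapping or multi-isoform genes, whole-genome
duplication structure, and promoter elements on the antisense strand.
Perfect planted-truth recovery therefore demonstrates that the pipeline's
logic and thresholds are internally consistent — not that the default
thresholds are optimal for any real genome.

Problem sizes in the tests and the acceptance script (the package's own
choice of desk scale): alignment oracles on 8–30-residue pairs (100+
seeded cases), pI oracle on 200 random peptides, NJ recovery up to 8 taxa,
bootstrap with 100 replicates, and the default synthetic genome above;
the full suite runs in about two minutes on one CPU.

## Command-line use

The exported stage functions are the primary interface. A thin wrapper at
`inst/scripts/famsurvey.R` provides `simulate` (write a synthetic dataset)
and `all` (run `run_survey()` on a YAML config); per-stage subcommands are
deliberately not duplicated in the CLI because each stage is a documented R
function already.

## Known limitations

* The NBD consensus check is weaker than a profile HMM for remote members.
* The hydropathy-window TM caller under-calls marginal helices.
* Progressive MSA quality degrades for deeply diverged families; distances
  feeding NJ are then underestimates even with the Poisson correction.
* Segmental detection is identity-based; no collinearity/synteny evidence
  is used, so it cannot distinguish segmental duplication from other
  high-identity paralogy.
* E-values in motif tables are carried as opaque text (printed values such
  as 10^−1822 underflow doubles) and are never computed on.
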