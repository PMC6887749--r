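Package: famsurvey
Title: Genome-Wide Gene Family Survey Pipeline for Annotated Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully scriptable re-implementation of the classic
    genome-wide gene-family survey: identification of ATP-binding-cassette
    (ABC) transporter family members in an annotated genome by local-alignment
    screening against seed queries followed by nucleotide-binding-domain motif
    confirmation (Walker A, ABC signature, Walker B), ProtParam-style protein
    characterization (molecular weight, isoelectric point, instability index,
    aliphatic index, GRAVY, hydropathy-window transmembrane segments),
    neighbor-joining phylogenies with bootstrap supports and reference-guided
    subfamily assignment, tandem and segmental duplication classification,
    extended-alphabet protein motif scanning, promoter extraction with
    cis-regulatory element scanning and allele comparison, and qPCR
    delta-delta-Ct expression summaries. Ships a synthetic-genome generator
    with planted ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
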