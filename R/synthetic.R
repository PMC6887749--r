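# Synthetic annotated genomes with planted ground truth.
#
# The generator emulates the setting of a multi-genome family survey at desk
# scale: multi-chromosome genomes carrying NBD-motif-bearing family genes,
# motif-free decoys, tandem clusters with at most one intervening gene,
# high-identity segmental pairs on different chromosomes, intronless genes,
# and promoters with planted cis-elements at recorded offsets.  Everything
# derives from one integer seed, so the same configuration is byte-identical
# across runs.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# NBD motif segments planted into every family protein
NBD_SEGMENTS <- list(walker_a = "GPSGSGKT", signature = "LSGGQ",
                     walker_b = "ILLLDE")

default_planted_elements <- function() {
  data.frame(element = c("W-box", "W-box", "ABRE", "MBS"),
             gene_index = c(1L, 2L, 1L, 3L),
             count = c(2L, 1L, 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic survey dataset
#'
#' Defaults describe the bundled study conditions: three chromosomes, twelve
#' family genes (two tandem clusters with one intervening decoy, two
#' cross-chromosome segmental pairs at 85% identity), eight decoys, a
#' quarter of genes intronless, and a handful of planted promoter elements.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome (bp).
#' @param n_family_genes Total family genes (includes duplication members).
#' @param n_decoy_genes Motif-free decoy genes.
#' @param n_tandem_clusters Tandem pairs to plant.
#' @param intervening_per_cluster 0 or 1 decoy genes between tandem members.
#' @param n_segmental_pairs Cross-chromosome high-identity pairs to plant.
#' @param segmental_identity Target identity of segmental pairs, in
#'   (0.8, 1].
#' @param intronless_fraction Probability that a gene has a single exon.
#' @param planted_elements Data frame (element, gene_index, count) of
#'   cis-elements planted into family-gene promoters.
#' @param rng_seed Integer seed driving every random choice.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 3L, chromosome_length = 120000L,
                             n_family_genes = 12L, n_decoy_genes = 8L,
                             n_tandem_clusters = 2L,
                             intervening_per_cluster = 1L,
                             n_segmental_pairs = 2L,
                             segmental_identity = 0.85,
                             intronless_fraction = 0.25,
                             planted_elements = default_planted_elements(),
                             rng_seed = 20191117L) {
  if (missing(planted_elements)) # default adapts to small family sizes
    planted_elements <-
      planted_elements[planted_elements$gene_index <= n_family_genes, ,
                       drop = FALSE]
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_family_genes = as.integer(n_family_genes),
              n_decoy_genes = as.integer(n_decoy_genes),
              n_tandem_clusters = as.integer(n_tandem_clusters),
              intervening_per_cluster = as.integer(intervening_per_cluster),
              n_segmental_pairs = as.integer(n_segmental_pairs),
              segmental_identity = segmental_identity,
              intronless_fraction = intronless_fraction,
              planted_elements = planted_elements,
              rng_seed = as.integer(rng_seed))
  counts <- cfg[c("n_chromosomes", "chromosome_length", "n_family_genes",
                  "n_decoy_genes", "n_tandem_clusters", "n_segmental_pairs")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (!cfg$intervening_per_cluster %in% c(0L, 1L))
    stop("intervening_per_cluster must be 0 or 1")
  if (cfg$n_segmental_pairs > 0L || cfg$n_tandem_clusters > 0L ||
      cfg$n_family_genes > 0L) {
    if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  }
  if (cfg$n_segmental_pairs > 0L && cfg$n_chromosomes < 2L)
    stop("segmental pairs need at least two chromosomes")
  if (!(cfg$segmental_identity > 0.8 && cfg$segmental_identity <= 1))
    stop("segmental_identity must lie in (0.8, 1]")
  if (cfg$intronless_fraction < 0 || cfg$intronless_fraction > 1)
    stop("intronless_fraction must lie in [0, 1]")
  need <- 2L * (cfg$n_tandem_clusters + cfg$n_segmental_pairs)
  if (cfg$n_family_genes < need)
    stop("n_family_genes must be at least ", need,
         " to host the requested duplication structure")
  if (cfg$n_tandem_clusters * cfg$intervening_per_cluster > cfg$n_decoy_genes)
    stop("not enough decoy genes to serve as intervening genes")
  if (nrow(planted_elements) &&
      any(planted_elements$gene_index > cfg$n_family_genes))
    stop("planted_elements gene_index exceeds n_family_genes")
  structure(cfg, class = "synthetic_config")
}

#' Mutate a protein to a target identity
#'
#' Substitution-only mutation (no indels): `round((1 - target) * L)`
#' positions, sampled outside `protected`, are replaced with a different
#' residue, so position-wise identity to the input is exact.
#'
#' @param seq Protein sequence.
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed.
#' @param protected Integer positions never mutated (e.g. planted motifs).
#' @return Mutated sequence of the same length.
#' @export
mutate_protein <- function(seq, target_identity, seed, protected = integer(0)) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  if (!(target_identity > 0 && target_identity <= 1))
    stop("target_identity must lie in (0, 1]")
  n <- nchar(seq)
  n_mut <- round((1 - target_identity) * n)
  if (n_mut == 0L) return(seq)
  free <- setdiff(seq_len(n), protected)
  if (length(free) < n_mut)
    stop("too few unprotected positions to reach the target identity")
  with_seed(seed, {
    pos <- sample(free, n_mut)
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(AA1, ch[p]), 1L)
    paste(ch, collapse = "")
  })
}

# random protein, no seed handling (caller manages RNG)
random_protein <- function(n) paste(sample(AA1, n, replace = TRUE),
                                    collapse = "")

# family prototype: leading Met, NBD triplet at fixed offsets
make_prototype <- function(len = 260L) {
  ch <- strsplit(random_protein(len), "")[[1]]
  ch[1] <- "M"
  put <- function(ch, seg, at) {
    s <- strsplit(seg, "")[[1]]
    ch[at:(at + length(s) - 1L)] <- s
    ch
  }
  ch <- put(ch, NBD_SEGMENTS$walker_a, 40L)
  ch <- put(ch, NBD_SEGMENTS$signature, 120L)
  ch <- put(ch, NBD_SEGMENTS$walker_b, 180L)
  protected <- c(1L, 40:47, 120:124, 180:185)
  list(seq = paste(ch, collapse = ""), protected = protected)
}

make_decoy_protein <- function(len) {
  repeat {
    p <- random_protein(len)
    substr(p, 1, 1) <- "M"
    if (!confirm_domain(p)$confirmed) return(p)
  }
}

# reverse the genetic code: codons per amino acid (deterministic order)
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

protein_to_cds <- function(protein, codons) {
  ch <- strsplit(protein, "")[[1]]
  picked <- vapply(ch, function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(picked, collapse = ""), "TAA")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Build the transcript-local structure of a gene: 5' UTR, CDS split by
# introns between complete codons.  Returns local intervals (1-based).
build_gene_body <- function(cds, intronless, utr_len = 50L) {
  n_introns <- if (intronless) 0L else sample(1:2, 1L)
  ncod <- nchar(cds) %/% 3L
  # split points after complete codons, interior only
  splits <- if (n_introns > 0L)
    sort(sample(seq_len(ncod - 1L), n_introns)) * 3L else integer(0)
  pieces <- list()
  prev <- 0L
  for (s in c(splits, nchar(cds))) {
    pieces[[length(pieces) + 1L]] <- substring(cds, prev + 1L, s)
    prev <- s
  }
  introns <- if (n_introns > 0L)
    vapply(seq_len(n_introns), function(i)
      paste0("GT", random_dna(sample(40:80, 1L)), "AG"), character(1))
  else character(0)

  seqparts <- character(0)
  exon_local <- list(); cds_local <- list()
  cursor <- 0L
  utr <- random_dna(utr_len)
  seqparts <- c(seqparts, utr)
  utr5_local <- c(1L, utr_len)
  cursor <- utr_len
  for (i in seq_along(pieces)) {
    st <- cursor + 1L
    en <- cursor + nchar(pieces[[i]])
    cds_local[[i]] <- c(st, en)
    exon_local[[i]] <- if (i == 1L) c(1L, en) else c(st, en)
    seqparts <- c(seqparts, pieces[[i]])
    cursor <- en
    if (i <= length(introns)) {
      seqparts <- c(seqparts, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  list(seq = paste(seqparts, collapse = ""),
       utr5 = utr5_local,
       exons = do.call(rbind, exon_local),
       cds = do.call(rbind, cds_local))
}

flip_intervals <- function(iv, body_len) {
  out <- cbind(body_len - iv[, 2] + 1L, body_len - iv[, 1] + 1L)
  out[order(out[, 1]), , drop = FALSE]
}

# instantiate an IUPAC pattern as a concrete sequence
instantiate_pattern <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(c0)
    sample(IUPAC_DNA[[c0]], 1L), character(1)), collapse = "")
}

# remove accidental dictionary matches from a promoter-sized window
clean_window <- function(seq, dictionary, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (r in seq_len(nrow(dictionary))) {
      pos <- count_element_hits(seq, dictionary$pattern[r])
      if (length(pos)) {
        dirty <- TRUE
        w <- nchar(dictionary$pattern[r])
        for (p in pos)
          substr(seq, p, p + w - 1L) <- random_dna(w)
      }
    }
    if (!dirty) return(seq)
  }
  stop("could not clean promoter background of dictionary matches")
}

#' Generate a synthetic survey dataset with planted truth
#'
#' Writes a genome FASTA, a GFF3 annotation, a proteome FASTA, the seed
#' query FASTA (the subfamily prototypes), truth tables (TSV) and a flat
#' key-value copy of the configuration into `dir`, and returns everything
#' in memory as well.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param dictionary Cis-element dictionary used for promoter cleaning and
#'   planting (default: the bundled starter dictionary).
#' @return List with `genome`, `models`, `proteome`, `queries`, `truth`,
#'   `paths`, `subfamily_of`.
#' @export
generate_survey_dataset <- function(config = synthetic_config(),
                                    dir = tempfile("synth"),
                                    dictionary = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(dictionary))
    dictionary <- read_cis_elements(system.file(
      "extdata", "cis_elements.tsv", package = "famsurvey", mustWork = TRUE))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  with_seed(config$rng_seed, {
    codons <- codons_by_aa()
    nfam <- config$n_family_genes
    ndec <- config$n_decoy_genes
    nt <- config$n_tandem_clusters
    ns <- config$n_segmental_pairs

    # -- subfamily prototypes (also the seed queries) ---------------------
    protos <- list(SynA = make_prototype(), SynG = make_prototype())
    subfams <- rep(names(protos), length.out = nfam)

    # -- family proteins by role ------------------------------------------
    fam_ids <- sprintf("fam%02d", seq_len(nfam))
    proteins <- stats::setNames(vector("list", nfam), fam_ids)
    tandem_truth <- list(); segmental_truth <- list()
    # pair slots: tandem clusters first, then segmental pairs, then singles
    slot <- 1L
    base_of <- function(sub) protos[[sub]]
    next_seed <- function() sample.int(2147483646L, 1L)
    primary_identity <- function() stats::runif(1, 0.60, 0.70)
    roles <- stats::setNames(rep("single", nfam), fam_ids)
    partner_of <- stats::setNames(rep(NA_character_, nfam), fam_ids)
    for (k in seq_len(nt)) {
      a <- fam_ids[slot]; b <- fam_ids[slot + 1L]
      roles[c(a, b)] <- "tandem"; partner_of[b] <- a
      subfams[slot + 1L] <- subfams[slot]
      slot <- slot + 2L
      tandem_truth[[k]] <- sort(c(a, b))
    }
    for (k in seq_len(ns)) {
      a <- fam_ids[slot]; b <- fam_ids[slot + 1L]
      roles[c(a, b)] <- "segmental"; partner_of[b] <- a
      subfams[slot + 1L] <- subfams[slot]
      slot <- slot + 2L
      segmental_truth[[k]] <- sort(c(a, b))
    }
    names(subfams) <- fam_ids
    for (i in seq_len(nfam)) {
      id <- fam_ids[i]
      if (is.na(partner_of[id])) {
        pr <- base_of(subfams[i])
        proteins[[id]] <- mutate_protein(pr$seq, primary_identity(),
                                         next_seed(), pr$protected)
      } else {
        pr <- base_of(subfams[i])
        src <- proteins[[partner_of[id]]]
        tgt <- if (roles[id] == "tandem") 0.90 else config$segmental_identity
        proteins[[id]] <- mutate_protein(src, tgt, next_seed(), pr$protected)
      }
    }

    dec_ids <- sprintf("dec%02d", seq_len(ndec))
    for (id in dec_ids) proteins[[id]] <- make_decoy_protein(sample(200:280, 1L))

    # -- gene bodies -------------------------------------------------------
    all_ids <- c(fam_ids, dec_ids)
    intronless_truth <- character(0)
    bodies <- stats::setNames(vector("list", length(all_ids)), all_ids)
    for (id in all_ids) {
      cds <- protein_to_cds(proteins[[id]], codons)
      il <- stats::runif(1) < config$intronless_fraction
      if (il) intronless_truth <- c(intronless_truth, id)
      bodies[[id]] <- build_gene_body(cds, il)
    }

    # -- placement: units per chromosome ----------------------------------
    # a unit is a vector of gene ids laid down consecutively
    units <- list()
    decoy_pool <- dec_ids
    take_decoy <- function() {
      if (!length(decoy_pool)) stop("not enough decoys for intervening genes")
      d <- decoy_pool[1]; decoy_pool <<- decoy_pool[-1]; d
    }
    seg_units <- list() # units pinned to distinct chromosomes
    slot <- 1L
    for (k in seq_len(nt)) {
      a <- fam_ids[slot]; b <- fam_ids[slot + 1L]; slot <- slot + 2L
      mid <- if (config$intervening_per_cluster == 1L) take_decoy() else NULL
      units[[length(units) + 1L]] <- c(a, mid, b)
    }
    for (k in seq_len(ns)) {
      a <- fam_ids[slot]; b <- fam_ids[slot + 1L]; slot <- slot + 2L
      seg_units[[length(seg_units) + 1L]] <- c(a, b)
    }
    for (id in fam_ids[slot:nfam][seq_len(max(0L, nfam - slot + 1L))])
      units[[length(units) + 1L]] <- id
    for (id in decoy_pool) units[[length(units) + 1L]] <- id

    chrom_ids <- sprintf("chr%d", seq_len(config$n_chromosomes))
    by_chrom <- stats::setNames(vector("list", length(chrom_ids)), chrom_ids)
    for (k in seq_along(seg_units)) {
      c1 <- chrom_ids[((2L * (k - 1L)) %% config$n_chromosomes) + 1L]
      c2 <- chrom_ids[((2L * (k - 1L) + 1L) %% config$n_chromosomes) + 1L]
      by_chrom[[c1]] <- c(by_chrom[[c1]], list(seg_units[[k]][1]))
      by_chrom[[c2]] <- c(by_chrom[[c2]], list(seg_units[[k]][2]))
    }
    if (length(units)) {
      loads <- vapply(by_chrom, function(u) sum(lengths(u)), numeric(1))
      for (u in units) {
        tgt <- which.min(loads)
        by_chrom[[tgt]] <- c(by_chrom[[tgt]], list(u))
        loads[tgt] <- loads[tgt] + length(u)
      }
    }

    # -- coordinates and genome assembly ----------------------------------
    pad_for <- function(id) if (startsWith(id, "fam")) 2100L else 300L
    genome <- stats::setNames(vapply(chrom_ids, function(x)
      random_dna(config$chromosome_length), character(1)), chrom_ids)
    models <- list()
    for (ch in chrom_ids) {
      cursor <- 0L
      prev_id <- NULL
      for (u in by_chrom[[ch]]) {
        for (id in u) {
          body <- bodies[[id]]
          # the gap before a gene must satisfy both its own upstream need
          # and the previous gene's downstream (promoter) need
          pad <- if (is.null(prev_id)) pad_for(id)
                 else max(pad_for(id), pad_for(prev_id))
          start <- cursor + pad + 1L
          len <- nchar(body$seq)
          end <- start + len - 1L
          if (end + pad > config$chromosome_length)
            stop("sizing error: chromosome_length ", config$chromosome_length,
                 " bp cannot hold the planted genes on ", ch,
                 " (need > ", end + pad, " bp)")
          strand <- sample(c("+", "-"), 1L)
          if (strand == "+") {
            bseq <- body$seq
            ex <- body$exons; cd <- body$cds; u5 <- matrix(body$utr5, ncol = 2)
          } else {
            bseq <- revcomp(body$seq)
            ex <- flip_intervals(body$exons, len)
            cd <- flip_intervals(body$cds, len)
            u5 <- flip_intervals(matrix(body$utr5, ncol = 2), len)
          }
          substr(genome[[ch]], start, end) <- bseq
          shift <- function(iv) cbind(iv[, 1] + start - 1L, iv[, 2] + start - 1L)
          models[[id]] <- gene_model(
            gene_id = id, chromosome = ch, strand = strand,
            start = start, end = end,
            exons = shift(ex), cds = shift(cd), utr5 = shift(u5))
          cursor <- end
          prev_id <- id
        }
      }
    }

    # -- promoter cleaning and element planting ---------------------------
    element_truth <- list()
    patt_of <- stats::setNames(dictionary$pattern, dictionary$name)
    planted <- config$planted_elements
    for (i in seq_len(nfam)) {
      id <- fam_ids[i]
      m <- models[[id]]
      if (m$strand == "+") {
        tss <- min(m$cds[, 1])
        win <- c(tss - 2000L, tss - 1L)
        sense <- substring(genome[[m$chromosome]], win[1], win[2])
      } else {
        tss <- max(m$cds[, 2])
        win <- c(tss + 1L, tss + 2000L)
        sense <- revcomp(substring(genome[[m$chromosome]], win[1], win[2]))
      }
      mine <- planted[planted$gene_index == i, , drop = FALSE]
      want <- stats::setNames(rep(0L, nrow(dictionary)), dictionary$name)
      if (nrow(mine))
        for (rr in seq_len(nrow(mine)))
          want[mine$element[rr]] <- want[mine$element[rr]] + mine$count[rr]
      # clean the background, plant at non-overlapping offsets, verify with
      # a direct scan; a planted instance abutting an unlucky background
      # base can spell a different element, so redraw until the scan agrees
      sense_raw <- sense
      ok <- FALSE
      for (attempt in 1:50) {
        sense <- clean_window(sense_raw, dictionary)
        if (nrow(mine)) {
          taken <- rep(FALSE, 2000L)
          row_of <- rep(seq_len(nrow(mine)), mine$count)
          for (rr in row_of) {
            w <- nchar(patt_of[[mine$element[rr]]])
            repeat {
              o <- sample.int(2000L - w + 1L, 1L)
              if (!any(taken[o:(o + w - 1L)])) break
            }
            taken[o:(o + w - 1L)] <- TRUE
            substr(sense, o, o + w - 1L) <-
              instantiate_pattern(patt_of[[mine$element[rr]]])
          }
        }
        got <- vapply(dictionary$name, function(nm)
          length(count_element_hits(sense, patt_of[[nm]])), integer(1))
        if (identical(unname(got), unname(want))) { ok <- TRUE; break }
      }
      if (!ok)
        stop("internal: planted element counts disagree with a direct scan")
      element_truth[[id]] <- want
      back <- if (m$strand == "+") sense else revcomp(sense)
      substr(genome[[m$chromosome]], win[1], win[2]) <- back
    }

    # -- outputs -----------------------------------------------------------
    proteome <- vapply(proteins, identity, character(1))
    queries <- vapply(protos, `[[`, character(1), "seq")
    paths <- list(
      genome = file.path(dir, "genome.fasta"),
      gff3 = file.path(dir, "annotation.gff3"),
      proteome = file.path(dir, "proteome.fasta"),
      queries = file.path(dir, "queries.fasta"),
      truth_dir = dir,
      config = file.path(dir, "config.txt"))
    write_fasta(genome, paths$genome)
    # GFF3 in chromosome/start order
    chroms <- vapply(models, `[[`, character(1), "chromosome")
    starts <- vapply(models, `[[`, integer(1), "start")
    lv <- unique(chroms)[natural_chrom_order(unique(chroms))]
    ord <- order(match(chroms, lv), starts)
    write_gff3(models[ord], paths$gff3)
    write_fasta(proteome, paths$proteome)
    write_fasta(queries, paths$queries)

    wt <- function(df, name)
      utils::write.table(df, file.path(dir, paste0("truth_", name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    wt(data.frame(gene_id = fam_ids, subfamily = unname(subfams[fam_ids]),
                  stringsAsFactors = FALSE), "family_members")
    pair_df <- function(lst) {
      if (!length(lst)) return(data.frame(gene_a = character(0),
                                          gene_b = character(0)))
      do.call(rbind, lapply(lst, function(p)
        data.frame(gene_a = p[1], gene_b = p[2], stringsAsFactors = FALSE)))
    }
    wt(pair_df(tandem_truth), "tandem_pairs")
    wt(pair_df(segmental_truth), "segmental_pairs")
    wt(data.frame(gene_id = sort(intronless_truth)), "intronless")
    ec <- do.call(rbind, lapply(fam_ids, function(id)
      data.frame(gene_id = id, element = names(element_truth[[id]]),
                 count = unname(element_truth[[id]]),
                 stringsAsFactors = FALSE)))
    wt(ec, "element_counts")

    scalars <- config[setdiff(names(config), "planted_elements")]
    pe <- config$planted_elements
    pe_str <- if (nrow(pe)) paste(sprintf("%s:%d:%d", pe$element,
                                          pe$gene_index, pe$count),
                                  collapse = ";") else ""
    writeLines(c(paste0(names(scalars), "=", unlist(scalars)),
                 paste0("planted_elements=", pe_str)), paths$config)

    truth <- list(family_members = fam_ids,
                  subfamily = subfams,
                  tandem_pairs = pair_df(tandem_truth),
                  segmental_pairs = pair_df(segmental_truth),
                  intronless = sort(intronless_truth),
                  element_counts = ec)
    list(genome = genome, models = models[ord], proteome = proteome,
         queries = queries, truth = truth, paths = paths,
         subfamily_of = subfams)
  })
}
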