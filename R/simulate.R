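#' Simulation configuration for the synthetic screen
#'
#' Builds the nested configuration used by all generators.  The defaults
#' describe the study conditions the pipeline is designed for: a compact,
#' gene-dense genome; alignment blocks whose GC content concentrates between
#' 0.30 and 0.60 and whose mean pairwise identity concentrates between 0.40
#' and 0.80; species counts peaking around 17-23 of 27; false motif calls
#' arising from one shared process on native and shuffled alignments with
#' planted true motifs on top (per-bin false discovery rate 0.1 at the
#' selection cutoff); and 80 expression experiments grouped as embryo (30),
#' larva (12), prepupa (6), adult (12) and cell lines (20), with a sixth of
#' features ubiquitously expressed.
#'
#' @param seed integer master seed; each generator derives its own sub-seed
#' @param genome,blocks,motifs,expression,orthology named lists overriding
#'   individual defaults (partial lists are merged into the defaults)
#' @return a list of class "SimulationConfig"
#' @export
simulationConfig <- function(seed = 1L, genome = list(), blocks = list(),
                             motifs = list(), expression = list(),
                             orthology = list()) {
  def <- list(
    seed = as.integer(seed),
    genome = list(
      n_chroms = 2L, chrom_length = 300000L, n_genes = 120L,
      frac_noncoding_genes = 0.1, n_ncrna = 60L,
      utr_ncrna_overlap_frac = 0.05, repeat_fraction = 0.05),
    blocks = list(
      target_coverage = 0.6, len_min = 40L, len_max = 800L,
      gc_shape1 = 12, gc_shape2 = 15,       # GC mass ~0.30-0.60
      id_shape1 = 10.8, id_shape2 = 7.2,    # identity mass ~0.40-0.80
      species_mean = 20, species_sd = 4, frac_low_species = 0.05),
    motifs = list(
      false_density_per_kb = 2, planted_fdr = 0.1, selection_cutoff = 80,
      false_pscore_rate = 1 / 15,           # false: 50 + Exp(rate)
      true_pscore_mean = 115, true_pscore_sd = 20,
      len_min = 30L, len_max = 150L, frac_true_in_ncrna = 0.3),
    expression = list(
      n_experiments = 80L,
      groups = c(embryo = 30L, larva = 12L, prepupa = 6L, adult = 12L,
                 cell_line = 20L),
      frac_ubiquitous = 1 / 6, frac_specific = 0.5,
      p_on_ubiquitous = 0.95, p_on_in_group = 0.9, p_on_background = 0.15,
      pair_n_on = 20L, dropout = 0.05),
    orthology = list(
      n_species = 11L, insertion_rate = 0.1, rearrangement_rate = 0.1,
      distance_inflation_rate = 0, inflated_distance = 25000L,
      missing_rate = 0.05, coordinate_jitter = 200L))
  for (sec in c("genome", "blocks", "motifs", "expression", "orthology")) {
    override <- get(sec)
    stopifnot(is.list(override))
    def[[sec]][names(override)] <- override
  }
  cfg <- def
  fr <- c(cfg$genome$frac_noncoding_genes, cfg$genome$utr_ncrna_overlap_frac,
          cfg$genome$repeat_fraction, cfg$blocks$target_coverage,
          cfg$motifs$planted_fdr, cfg$expression$frac_ubiquitous,
          cfg$expression$frac_specific, cfg$expression$dropout)
  if (any(fr < 0 | fr > 1))
    .crsStop("all fractions in the configuration must lie in [0, 1]",
             "crsConfigError")
  if (sum(cfg$expression$groups) != cfg$expression$n_experiments)
    .crsStop("experiment group sizes must sum to n_experiments",
             "crsConfigError")
  structure(cfg, class = "SimulationConfig")
}

## per-generator sub-seeds so each generator is deterministic whether called
## alone or in sequence
.generatorSeed <- function(config, which) {
  seeds <- .subSeeds(config$seed, 4L)
  seeds[match(which, c("genome", "motifs", "expression", "orthology"))]
}

#' Simulate a gene-dense annotated genome
#'
#' Places protein-coding and non-coding genes with exon/intron/UTR structure
#' along each chromosome, ncRNA features (a configurable fraction of UTR-exon
#' nucleotides is overlapped by ncRNA exons), and a repeat track covering a
#' configurable genome fraction.  Deterministic given the config seed.
#'
#' @param config a [simulationConfig()]
#' @return list with elements geneModels (GFF-style GRanges: gene/exon/CDS
#'   rows with ID/Parent), genes (gene spans with coding flag), ncrna (GRanges
#'   with id, class, bp_content), repeats (merged GRanges), seqlengths
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.generatorSeed(config, "genome"))
  g <- config$genome
  chroms <- sprintf("chrS%d", seq_len(g$n_chroms))
  seqlengths <- setNames(rep(g$chrom_length, g$n_chroms), chroms)

  perChrom <- diff(round(seq(0, g$n_genes, length.out = g$n_chroms + 1)))
  rows <- list()
  geneCounter <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- round(runif(1, 500, 2000))
    for (k in seq_len(perChrom[ci])) {
      geneCounter <- geneCounter + 1L
      coding <- runif(1) > g$frac_noncoding_genes
      gid <- sprintf("G%04d", geneCounter)
      strand <- sample(c("+", "-"), 1L)
      if (coding) {
        nEx <- 1L + rpois(1, 1.2)
        utr5 <- round(runif(1, 60, 150))
        utr3 <- round(runif(1, 100, 300))
        if (nEx == 1L) {
          exLens <- utr5 + utr3 + round(runif(1, 150, 400))
        } else {
          exLens <- round(runif(nEx, 120, 400))
          exLens[1] <- utr5 + round(runif(1, 50, 200))
          exLens[nEx] <- utr3 + round(runif(1, 50, 200))
        }
      } else {
        nEx <- sample(1:2, 1L)
        exLens <- round(runif(nEx, 100, 400))
        utr5 <- utr3 <- 0L
      }
      intLens <- if (nEx > 1L) round(runif(nEx - 1L, 60, 1500)) else integer(0)
      span <- sum(exLens) + sum(intLens)
      if (cursor + span > seqlengths[ci] - 500) {
        if (geneCounter <= g$n_genes)
          .crsStop(paste("infeasible packing: requested genes exceed",
                         "chromosome length"), "crsConfigError")
        break
      }
      exStarts <- cursor + cumsum(c(0, head(exLens, -1) + intLens))
      exEnds <- exStarts + exLens - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = c(cursor, exStarts),
        end = c(cursor + span - 1L, exEnds), strand = strand,
        type = c("gene", rep("exon", nEx)),
        ID = c(gid, sprintf("%s.E%d", gid, seq_len(nEx))),
        Parent = c(NA, rep(gid, nEx)), coding = coding)
      if (coding) {
        ## CDS = exon parts minus the UTR ends (5' at transcription start)
        gStart <- cursor; gEnd <- cursor + span - 1L
        if (strand == "+") {
          cdsFrom <- gStart + utr5; cdsTo <- gEnd - utr3
        } else {
          cdsFrom <- gStart + utr3; cdsTo <- gEnd - utr5
        }
        cs <- pmax(exStarts, cdsFrom); ce <- pmin(exEnds, cdsTo)
        keep <- cs <= ce
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chroms[ci], start = cs[keep], end = ce[keep],
            strand = strand, type = "CDS",
            ID = sprintf("%s.C%d", gid, seq_len(sum(keep))), Parent = gid,
            coding = TRUE)
      }
      cursor <- cursor + span + round(runif(1, 500, 3000))
    }
  }
  df <- do.call(rbind, rows)
  geneModels <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID, Parent = df$Parent, coding = df$coding,
    seqlengths = seqlengths)

  genes <- geneModels[geneModels$type == "gene"]

  ## ncRNA features: some overlap UTR exons (target nt fraction), the rest
  ## land anywhere (introns and intergenic space)
  classes <- c("tRNA", "miRNA", "rRNA", "CD_snoRNA", "HACA_snoRNA", "scaRNA",
               "snRNA", "lncRNA", "cis_regulatory", "SRP_RNA",
               "histone_stem_loop", "ribozyme", "retroelement")
  utrExons <- .utrExonRanges(geneModels)
  ncRows <- list()
  target <- g$utr_ncrna_overlap_frac * sum(GenomicRanges::width(utrExons))
  covered <- 0
  shuffledUtr <- if (length(utrExons)) sample(seq_along(utrExons)) else integer(0)
  ui <- 1L
  while (covered < target && ui <= length(shuffledUtr)) {
    u <- utrExons[shuffledUtr[ui]]; ui <- ui + 1L
    len <- round(runif(1, 80, 150))
    ovLen <- min(len, GenomicRanges::width(u))
    st <- GenomicRanges::start(u) +
      sample(0:max(0, GenomicRanges::width(u) - ovLen), 1L)
    ncRows[[length(ncRows) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(u)), start = st,
      end = st + len - 1L)
    covered <- covered + ovLen
  }
  nFree <- max(0L, g$n_ncrna - length(ncRows))
  if (nFree > 0) {
    ## free ncRNAs avoid UTR exons so the targeted overlap fraction stays
    ## where it was configured
    placed <- 0L
    tries <- 0L
    while (placed < nFree && tries < 50L * nFree) {
      tries <- tries + 1L
      chr <- sample(chroms, 1L)
      len <- round(runif(1, 70, 300))
      st <- round(runif(1, 1, seqlengths[chr] - len - 1))
      cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + len - 1L),
                                     seqlengths = seqlengths)
      if (length(utrExons) &&
          IRanges::overlapsAny(cand, utrExons, ignore.strand = TRUE))
        next
      ncRows[[length(ncRows) + 1L]] <- data.frame(chrom = chr, start = st,
                                                  end = st + len - 1L)
      placed <- placed + 1L
    }
  }
  ncDf <- do.call(rbind, ncRows)
  ncrna <- GenomicRanges::GRanges(ncDf$chrom,
                                  IRanges::IRanges(ncDf$start, ncDf$end),
                                  seqlengths = seqlengths)
  ncrna <- ncrna[GenomicRanges::end(ncrna) <= seqlengths[
    as.character(GenomeInfoDb::seqnames(ncrna))]]
  ncrna$id <- sprintf("NC%04d", seq_along(ncrna))
  ncrna$class <- sample(classes, length(ncrna), replace = TRUE)
  ncrna$bp_content <- rbeta(length(ncrna), 4, 2)

  ## repeats: random intervals until the target coverage is reached
  reps <- GenomicRanges::GRanges(seqlengths = seqlengths)
  targetRep <- g$repeat_fraction * sum(as.numeric(seqlengths))
  while (sum(GenomicRanges::width(reps)) < targetRep) {
    chr <- sample(chroms, 20L, replace = TRUE)
    len <- round(runif(20L, 100, 500))
    st <- round(runif(20L, 1, seqlengths[chr] - len - 1))
    add <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + len - 1L),
                                  seqlengths = seqlengths)
    reps <- GenomicRanges::reduce(c(reps, add))
  }

  list(geneModels = geneModels, genes = genes, ncrna = ncrna, repeats = reps,
       seqlengths = seqlengths)
}

## UTR exon parts of coding genes (exon minus CDS), stranded input,
## unstranded output; helper shared with unifyAnnotation
.utrExonRanges <- function(geneModels) {
  ex <- geneModels[geneModels$type == "exon" &
                     geneModels$Parent %in%
                       geneModels$ID[geneModels$type == "gene" &
                                       geneModels$coding]]
  cds <- geneModels[geneModels$type == "CDS"]
  GenomicRanges::setdiff(
    GenomicRanges::reduce(BiocGenerics::unstrand(ex)),
    GenomicRanges::reduce(BiocGenerics::unstrand(cds)))
}

#' Simulate alignment-block metadata and native/shuffled motif predictions
#'
#' Blocks tile a configurable fraction of the genome with GC and identity
#' drawn from beta distributions and species counts peaked around 17-23.
#' False motif calls are drawn from one shared per-block Poisson process with
#' two independent streams, one labelled native and one shuffled (the
#' shuffled-alignment logic: composition retained, structure signal
#' destroyed, so only the false-generating process remains).  True motifs are
#' added to the native stream only, at a density solved so that the expected
#' per-bin FDR at the selection cutoff equals \code{planted_fdr}; they are
#' placed preferentially inside annotated ncRNA features.
#'
#' @param config a [simulationConfig()]
#' @param genome output of [simulateGenome()]
#' @return list with blocks (GRanges: n_species, gc, identity), native and
#'   shuffled motif GRanges (id, pscore, energy, gc, identity, n_species,
#'   source), and groundTruth (true motif ids, planted FDR, densities)
#' @export
simulateBlocksAndMotifs <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.generatorSeed(config, "motifs"))
  b <- config$blocks
  m <- config$motifs
  seqlengths <- genome$seqlengths

  rows <- list()
  for (chr in names(seqlengths)) {
    cursor <- 1L
    L <- seqlengths[[chr]]
    meanLen <- (b$len_min + b$len_max) / 2
    meanGap <- meanLen * (1 / b$target_coverage - 1)
    while (cursor < L - b$len_max) {
      len <- round(runif(1, b$len_min, b$len_max))
      rows[[length(rows) + 1L]] <- data.frame(chrom = chr, start = cursor,
                                              end = cursor + len - 1L)
      cursor <- cursor + len + round(runif(1, 0, 2 * meanGap))
    }
  }
  df <- do.call(rbind, rows)
  blocks <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end),
                                   seqlengths = seqlengths)
  ns <- round(rnorm(length(blocks), b$species_mean, b$species_sd))
  ns <- .clamp(ns, 3L, 27L)
  low <- runif(length(blocks)) < b$frac_low_species
  ns[low] <- sample(1:2, sum(low), replace = TRUE)
  blocks$n_species <- as.integer(ns)
  blocks$gc <- rbeta(length(blocks), b$gc_shape1, b$gc_shape2)
  blocks$identity <- rbeta(length(blocks), b$id_shape1, b$id_shape2)

  ## predictions exist only for blocks that passed the screen's input filter
  usable <- blocks[GenomicRanges::width(blocks) >= 50 & blocks$n_species >= 3]

  sf <- exp(-(m$selection_cutoff - 50) * m$false_pscore_rate)
  st <- 1 - pnorm(m$selection_cutoff, m$true_pscore_mean, m$true_pscore_sd)
  trueDensity <- if (m$planted_fdr <= 0) 0 else
    m$false_density_per_kb * sf * (1 - m$planted_fdr) / (m$planted_fdr * st)

  drawFalse <- function(source, offset) {
    counts <- rpois(length(usable),
                    GenomicRanges::width(usable) / 1000 *
                      m$false_density_per_kb)
    bi <- rep(seq_along(usable), counts)
    n <- length(bi)
    if (n == 0L) return(.emptyMotifs(seqlengths))
    .makeMotifs(usable, bi, pscore = 50 + rexp(n, m$false_pscore_rate),
                source = source, prefix = offset, config = config,
                inNcrna = NULL)
  }
  native <- drawFalse("native", "MN")
  shuffled <- drawFalse("shuffled", "MS")

  tCounts <- rpois(length(usable),
                   GenomicRanges::width(usable) / 1000 * trueDensity)
  bi <- rep(seq_along(usable), tCounts)
  trueIds <- character(0)
  if (length(bi)) {
    ps <- rnorm(length(bi), m$true_pscore_mean, m$true_pscore_sd)
    while (any(ps <= 50))
      ps[ps <= 50] <- rnorm(sum(ps <= 50), m$true_pscore_mean,
                            m$true_pscore_sd)
    trueMotifs <- .makeMotifs(usable, bi, pscore = ps, source = "native",
                              prefix = "MT", config = config,
                              inNcrna = genome$ncrna)
    trueIds <- trueMotifs$id
    native <- c(native, trueMotifs)
  }
  native <- BiocGenerics::sort(native, ignore.strand = TRUE)

  list(blocks = blocks, native = native, shuffled = shuffled,
       groundTruth = list(true_ids = trueIds, planted_fdr = m$planted_fdr,
                          true_density_per_kb = trueDensity,
                          false_density_per_kb = m$false_density_per_kb))
}

.emptyMotifs <- function(seqlengths) {
  gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = character(0), pscore = numeric(0), energy = numeric(0),
    gc = numeric(0), identity = numeric(0), n_species = integer(0),
    source = character(0))
  gr
}

## place motifs inside their blocks; a fraction of true motifs is anchored on
## ncRNA features intersecting the block
.makeMotifs <- function(blocks, blockIdx, pscore, source, prefix, config,
                        inNcrna = NULL) {
  m <- config$motifs
  n <- length(blockIdx)
  bl <- blocks[blockIdx]
  len <- pmin(round(runif(n, m$len_min, m$len_max)),
              GenomicRanges::width(bl))
  st <- GenomicRanges::start(bl) +
    floor(runif(n) * (GenomicRanges::width(bl) - len + 1))
  if (!is.null(inNcrna) && length(inNcrna)) {
    anchor <- runif(n) < m$frac_true_in_ncrna
    ov <- GenomicRanges::findOverlaps(bl, inNcrna, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ov))
    map <- rep(NA_integer_, length(bl))
    map[S4Vectors::queryHits(ov)[first]] <- S4Vectors::subjectHits(ov)[first]
    hit <- which(anchor & !is.na(map))
    if (length(hit)) {
      anchors <- inNcrna[map[hit]]
      st[hit] <- .clamp(GenomicRanges::start(anchors),
                        GenomicRanges::start(bl[hit]),
                        GenomicRanges::end(bl[hit]) - len[hit] + 1L)
    }
  }
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(bl), IRanges::IRanges(st, st + len - 1L),
    strand = sample(c("+", "-"), n, replace = TRUE),
    seqlengths = GenomeInfoDb::seqlengths(blocks))
  gr$id <- sprintf("%s%06d", prefix, seq_len(n))
  gr$pscore <- pscore
  gr$energy <- rnorm(n, -10, 4)
  gr$gc <- .clamp(bl$gc + rnorm(n, 0, 0.02), 0, 1)
  gr$identity <- .clamp(bl$identity + rnorm(n, 0, 0.02), 0, 1)
  gr$n_species <- bl$n_species
  gr$source <- source
  gr
}

#' Simulate expression experiments over a set of features
#'
#' Assigns each feature a ground-truth pattern over the experiments:
#' ubiquitous (on in ~95% of experiments), stage/cell-line specific (on only
#' within one group), or sparse background.  Planted CRS-gene pairs override
#' the patterns of their two members so that the co-expression score computed
#' downstream equals the target exactly at zero noise.  Noise is modelled as
#' detection dropout: each true "on" call is missed independently with
#' probability \code{dropout} (tiling arrays under-detect; spurious calls are
#' not modelled).  Per-experiment transcript-region tracks are the merged
#' intervals of the features observed "on".
#'
#' @param config a [simulationConfig()]
#' @param features GRanges with an \code{id} metadata column
#' @param pairs optional data.frame(crs_id, gene_id, target) of planted
#'   co-expressed pairs; ids must appear in \code{features}
#' @param dropout overrides the config dropout probability
#' @return list with meta (experiment metadata data.frame), patterns (clean
#'   logical matrix features x experiments), observed (after dropout), tracks
#'   (named list of merged GRanges per experiment), groundTruth (pattern
#'   class per feature, planted pair table)
#' @export
simulateExpression <- function(config, features, pairs = NULL,
                               dropout = NULL) {
  stopifnot(inherits(config, "SimulationConfig"), is(features, "GRanges"))
  if (is.null(features$id))
    .crsStop("features need an 'id' metadata column", "crsValidationError")
  set.seed(.generatorSeed(config, "expression"))
  e <- config$expression
  if (is.null(dropout)) dropout <- e$dropout
  nExp <- e$n_experiments
  meta <- data.frame(
    experiment = sprintf("E%03d", seq_len(nExp)),
    stage_group = rep(names(e$groups), e$groups),
    sample_class = rep(ifelse(names(e$groups) == "cell_line", "cell_line",
                              "fly"), e$groups),
    strain = rep_len(c("strainA", "strainB"), nExp),
    compartment = NA_character_,
    rna_fraction = rep_len(c("total", "polyA", "nuclear"), nExp))

  n <- length(features)
  u <- runif(n)
  class <- ifelse(u < e$frac_ubiquitous, "ubiquitous",
                  ifelse(u < e$frac_ubiquitous + e$frac_specific, "specific",
                         "background"))
  group <- sample(names(e$groups), n, replace = TRUE)
  pat <- matrix(FALSE, n, nExp,
                dimnames = list(features$id, meta$experiment))
  inGroup <- outer(group, meta$stage_group, "==")
  r <- matrix(runif(n * nExp), n, nExp)
  pat[class == "ubiquitous", ] <-
    r[class == "ubiquitous", , drop = FALSE] < e$p_on_ubiquitous
  sp <- class == "specific"
  pat[sp, ] <- inGroup[sp, , drop = FALSE] &
    (r[sp, , drop = FALSE] < e$p_on_in_group)
  bg <- class == "background"
  pat[bg, ] <- r[bg, , drop = FALSE] < e$p_on_background

  if (!is.null(pairs) && nrow(pairs)) {
    miss <- setdiff(c(pairs$crs_id, pairs$gene_id), features$id)
    if (length(miss))
      .crsStop(paste("planted pair ids not among features:",
                     paste(head(miss, 3), collapse = ", ")),
               "crsConfigError")
    for (k in seq_len(nrow(pairs))) {
      t <- pairs$target[k]
      on <- sort(sample(nExp, e$pair_n_on))
      off <- setdiff(seq_len(nExp), on)
      crsVec <- geneVec <- rep(FALSE, nExp)
      crsVec[on] <- TRUE
      if (t >= 0) {
        geneVec[on[seq_len(round(t * length(on)))]] <- TRUE
      } else {
        geneVec[off[seq_len(round(-t * length(off)))]] <- TRUE
      }
      pat[pairs$crs_id[k], ] <- crsVec
      pat[pairs$gene_id[k], ] <- geneVec
      class[match(c(pairs$crs_id[k], pairs$gene_id[k]), features$id)] <-
        "planted_pair"
    }
  }

  observed <- pat & (matrix(runif(n * nExp), n, nExp) >= dropout)
  tracks <- lapply(seq_len(nExp), function(j) {
    mergeTrack(features[observed[, j]], maxGap = 0L)
  })
  names(tracks) <- meta$experiment

  list(meta = meta, patterns = pat, observed = observed, tracks = tracks,
       groundTruth = list(pattern_class = setNames(class, features$id),
                          group = setNames(group, features$id),
                          pairs = pairs, dropout = dropout))
}

#' Simulate per-species gene arrangements and an ortholog table
#'
#' Each of the \code{n_species} companion species receives a jittered copy of
#' the focal gene annotation (order preserved) plus the focal positions of
#' the tracked CRS loci.  Per tracked CRS-gene pair and species,
#' rearrangement events are applied: with \code{insertion_rate} an extra gene
#' is inserted between CRS and ortholog (breaks the strict closest-gene
#' criterion but not orientation); with \code{rearrangement_rate} the
#' ortholog is mirrored to the other side of the CRS (breaks orientation);
#' with \code{distance_inflation_rate} the ortholog is moved
#' \code{inflated_distance} nt away on the same side (breaks the distance
#' criterion).  Orthologs are missing at \code{missing_rate}.
#'
#' @param config a [simulationConfig()]
#' @param genes GRanges of focal gene spans with \code{ID}
#' @param crs GRanges of tracked CRS loci with \code{id}
#' @param pairs data.frame(crs_id, gene_id) of tracked pairs
#' @return list with orthologs (data.frame gene_id, species, ortholog_id),
#'   speciesGenes (per-species GRanges with id, ortholog_of), speciesCrs
#'   (per-species GRanges with id), events (per pair x species event label)
#' @export
simulateOrthology <- function(config, genes, crs, pairs) {
  stopifnot(inherits(config, "SimulationConfig"), is(genes, "GRanges"),
            is(crs, "GRanges"))
  set.seed(.generatorSeed(config, "orthology"))
  o <- config$orthology
  species <- sprintf("S%02d", seq_len(o$n_species))
  orthologs <- list(); speciesGenes <- list(); speciesCrs <- list()
  events <- list()
  ## species coordinate systems are unconstrained: drop focal seqlengths so
  ## shifts cannot run out of bounds
  genes0 <- genes
  GenomeInfoDb::seqlengths(genes0) <- NA
  crs0 <- crs
  GenomeInfoDb::seqlengths(crs0) <- NA
  for (sp in species) {
    shift <- round(rnorm(length(genes0), 0, o$coordinate_jitter))
    sg <- GenomicRanges::shift(genes0, shift)
    sg$id <- paste0(sg$ID, "@", sp)
    sg$ortholog_of <- sg$ID
    present <- runif(length(sg)) >= o$missing_rate
    sc <- GenomicRanges::shift(
      crs0, round(rnorm(length(crs0), 0, o$coordinate_jitter)))
    for (k in seq_len(nrow(pairs))) {
      gi <- match(pairs$gene_id[k], sg$ortholog_of)
      ci <- match(pairs$crs_id[k], sc$id)
      if (is.na(gi) || is.na(ci) || !present[gi]) {
        events[[length(events) + 1L]] <- data.frame(
          crs_id = pairs$crs_id[k], species = sp, event = "missing")
        next
      }
      u <- runif(1)
      ev <- "none"
      crsMid <- (GenomicRanges::start(sc[ci]) + GenomicRanges::end(sc[ci])) %/% 2
      if (u < o$insertion_rate) {
        ev <- "insertion"
        gapLo <- min(GenomicRanges::end(sc[ci]), GenomicRanges::end(sg[gi]))
        gapHi <- max(GenomicRanges::start(sc[ci]),
                     GenomicRanges::start(sg[gi]))
        if (gapHi - gapLo > 80) {
          ins <- sg[gi]   # template row: same mcols layout
          GenomicRanges::ranges(ins) <- IRanges::IRanges(
            gapLo + 10L, min(gapHi - 10L, gapLo + 10L + 200L))
          ins$ID <- sprintf("INS_%s_%s", pairs$crs_id[k], sp)
          ins$id <- paste0(ins$ID, "@", sp)
          ins$ortholog_of <- NA_character_
          sg <- c(sg, ins)
          present <- c(present, TRUE)
        }
      } else if (u < o$insertion_rate + o$rearrangement_rate) {
        ev <- "mirror"
        offset <- GenomicRanges::start(sg[gi]) - crsMid
        newStart <- crsMid - offset - GenomicRanges::width(sg[gi]) + 1L
        sg[gi] <- GenomicRanges::shift(sg[gi],
                                       newStart - GenomicRanges::start(sg[gi]))
      } else if (u < o$insertion_rate + o$rearrangement_rate +
                   o$distance_inflation_rate) {
        ev <- "inflate"
        dir <- if (GenomicRanges::start(sg[gi]) >= crsMid) 1L else -1L
        sg[gi] <- GenomicRanges::shift(sg[gi], dir * o$inflated_distance)
      }
      events[[length(events) + 1L]] <- data.frame(
        crs_id = pairs$crs_id[k], species = sp, event = ev)
    }
    sg <- sg[present]
    sg <- GenomicRanges::trim(sg)
    sg <- sg[GenomicRanges::width(sg) > 0]
    speciesGenes[[sp]] <- sg
    speciesCrs[[sp]] <- GenomicRanges::trim(sc)
    orthologs[[sp]] <- data.frame(gene_id = sg$ortholog_of[
      !is.na(sg$ortholog_of)], species = sp,
      ortholog_id = sg$id[!is.na(sg$ortholog_of)])
  }
  list(orthologs = do.call(rbind, orthologs), speciesGenes = speciesGenes,
       speciesCrs = speciesCrs, events = do.call(rbind, events))
}
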