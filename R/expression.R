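#' The "expressed" predicate
#'
#' A feature is expressed in an experiment when it overlaps the experiment's
#' merged transcript regions by at least \code{minFrac} of its own size
#' (default 0.5; set 1.0 for the strict full-containment variant).
#'
#' @param features GRanges
#' @param experimentRegions merged transcript-region GRanges of one
#'   experiment
#' @param minFrac covered-fraction threshold (inclusive)
#' @return logical vector, one flag per feature
#' @export
isExpressed <- function(features, experimentRegions, minFrac = 0.5) {
  coverageFraction(features, experimentRegions) >= minFrac
}

#' Build the boolean expression matrix
#'
#' Applies [isExpressed()] to every feature in every experiment.  Transcript
#' regions are merged per experiment (gap 0) before coverage computation.
#' The result is a RangedSummarizedExperiment whose single assay "expressed"
#' is a logical features x experiments matrix, with the experiment metadata
#' as colData.
#'
#' @param features GRanges with an \code{id} metadata column
#' @param tracks named list of per-experiment transcript-region GRanges
#' @param meta data.frame of experiment metadata with an \code{experiment}
#'   column matching \code{names(tracks)}
#' @param minFrac threshold passed to [isExpressed()]
#' @return a [SummarizedExperiment::RangedSummarizedExperiment]
#' @export
buildExpressionMatrix <- function(features, tracks, meta = NULL,
                                  minFrac = 0.5) {
  validateTrack(features, "features")
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (is.null(features$id))
    .crsStop("features need an 'id' metadata column", "crsValidationError")
  empty <- vapply(tracks, length, integer(1)) == 0L
  if (any(empty))
    warning(sum(empty), " experiment(s) have empty transcript tracks")
  mat <- vapply(tracks, function(tr) {
    isExpressed(features, mergeTrack(tr, maxGap = 0L), minFrac = minFrac)
  }, logical(length(features)))
  if (length(features) == 1L)
    mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(tracks)))
  rownames(mat) <- features$id
  if (is.null(meta))
    meta <- data.frame(experiment = names(tracks))
  stopifnot(identical(meta$experiment, names(tracks)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expressed = mat), rowRanges = features,
    colData = S4Vectors::DataFrame(meta, row.names = meta$experiment))
}

#' Extract the logical expression matrix from the container
#'
#' @param se a SummarizedExperiment built by [buildExpressionMatrix()]
#' @export
expressedMatrix <- function(se) {
  SummarizedExperiment::assay(se, "expressed")
}

#' Expression enrichment of CRS loci against sampled genomic windows
#'
#' Tiles the genome into non-overlapping windows, samples as many windows as
#' there are loci under consideration, and tests whether expressed windows
#' are enriched for CRS overlap with a one-sided Fisher exact test on the
#' 2x2 table (window expressed in >= k experiments vs not) x (window
#' overlapping a locus by >= 50% of window-or-locus size vs not).  Sampling
#' and testing are repeated \code{nSamples} times with derived sub-seeds and
#' the largest p-value is reported per minimum experiment count.  The
#' filtered variant removes windows and loci overlapping coding or UTR exons
#' by >= 1 bp before testing, to avoid mRNA exon bias.
#'
#' @param loci CRS locus GRanges
#' @param seqlengths named chromosome lengths
#' @param tracks per-experiment merged transcript-region GRanges
#' @param window window size in nt (default 100)
#' @param nSamples sampling replicates (default 10)
#' @param minExperiments vector of minimum experiment counts (default 1:4)
#' @param excludeExonic logical; apply the coding/UTR-exon filter
#' @param unified a [UnifiedAnnotation-class], required when
#'   \code{excludeExonic}
#' @param seed integer seed for the replicate sub-seeds
#' @return data.frame(min_experiments, max_p, n_windows, n_loci); max_p is
#'   the largest one-sided Fisher p over the replicates
#' @export
expressionEnrichment <- function(loci, seqlengths, tracks, window = 100L,
                                 nSamples = 10L, minExperiments = 1:4,
                                 excludeExonic = FALSE, unified = NULL,
                                 seed = 1L) {
  validateTrack(loci, "loci")
  tiles <- GenomicRanges::tileGenome(seqlengths, tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  if (excludeExonic) {
    if (is.null(unified))
      .crsStop("excludeExonic requires the unified annotation",
               "crsValidationError")
    seg <- annotationSegments(unified)
    exonic <- seg[seg$category %in% c("coding_exon", "utr5_exon",
                                      "utr3_exon", "both_utr_exon")]
    tiles <- tiles[!IRanges::overlapsAny(tiles, exonic,
                                         ignore.strand = TRUE)]
    loci <- loci[!IRanges::overlapsAny(loci, exonic, ignore.strand = TRUE)]
  }
  if (length(loci) == 0L)
    .crsStop("no loci left to test", "crsValidationError")
  nDraw <- min(length(loci), length(tiles))
  ## per-window count of experiments in which the window is expressed
  tileExpr <- matrix(FALSE, length(tiles), length(tracks))
  for (j in seq_along(tracks))
    tileExpr[, j] <- isExpressed(tiles, mergeTrack(tracks[[j]], 0L))
  tileCounts <- rowSums(tileExpr)
  ov <- overlapPairs(tiles, loci, minFracQuery = 0.5, minFracTarget = 0.5,
                     eitherSuffices = TRUE)
  crsHit <- logical(length(tiles))
  crsHit[unique(ov$queryIdx)] <- TRUE

  seeds <- .subSeeds(seed, nSamples)
  rows <- lapply(minExperiments, function(k) {
    ps <- vapply(seq_len(nSamples), function(r) {
      set.seed(seeds[r])
      idx <- sample(length(tiles), nDraw)
      expressed <- tileCounts[idx] >= k
      hit <- crsHit[idx]
      tab <- table(factor(expressed, levels = c(TRUE, FALSE)),
                   factor(hit, levels = c(TRUE, FALSE)))
      fisherEnrichmentP(tab)
    }, numeric(1))
    data.frame(min_experiments = k, max_p = max(ps), n_windows = nDraw,
               n_loci = length(loci))
  })
  do.call(rbind, rows)
}

## one-sided Fisher exact p for enrichment of cell [1,1] in a 2x2 table;
## degenerate margins give p = 1 with a warning
fisherEnrichmentP <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table; p = 1")
    return(1)
  }
  fisher.test(tab, alternative = "greater")$p.value
}
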