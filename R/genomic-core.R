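#' Merge an interval track
#'
#' Collapses intervals separated by at most \code{maxGap} nucleotides into
#' single intervals, optionally per strand.  With \code{strandAware = FALSE}
#' (the default) intervals on opposite strands are merged and the result is
#' unstranded.  The gap between two intervals is the number of nucleotides
#' strictly between them, so touching or overlapping intervals always merge.
#' Merging is idempotent.
#'
#' @param track a [GenomicRanges::GRanges]
#' @param maxGap non-negative integer; intervals with gap <= maxGap merge
#' @param strandAware if TRUE, only same-strand intervals merge
#' @return a merged, sorted GRanges whose intervals are pairwise disjoint
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'                              IRanges::IRanges(c(101, 162), c(160, 220)),
#'                              strand = c("+", "-"))
#' mergeTrack(gr, maxGap = 30)   # one unstranded interval 101-220
#' @export
mergeTrack <- function(track, maxGap = 0L, strandAware = FALSE) {
  stopifnot(is(track, "GRanges"))
  if (length(maxGap) != 1L || is.na(maxGap) || maxGap < 0)
    .crsStop("maxGap must be a single non-negative integer", "crsValidationError")
  if (length(track) == 0L)
    return(track)
  GenomicRanges::reduce(track, min.gapwidth = maxGap + 1L,
                        ignore.strand = !strandAware)
}

#' Fraction of a query interval covered by a merged target track
#'
#' Returns, for each query interval, the fraction of its nucleotides covered
#' by the target track.  Targets must already be merged (pairwise disjoint,
#' per strand when \code{strandAware}); otherwise overlapping targets would be
#' double counted and an error is raised.
#'
#' @param query a GRanges of query intervals
#' @param targets a merged GRanges
#' @param strandAware if TRUE, only same-strand coverage counts
#' @return numeric vector in [0, 1], one value per query
#' @export
coverageFraction <- function(query, targets, strandAware = FALSE) {
  stopifnot(is(query, "GRanges"), is(targets, "GRanges"))
  if (!IRanges::isDisjoint(targets, ignore.strand = !strandAware))
    .crsStop("targets must be merged (disjoint); call mergeTrack() first",
             "crsUnmergedTargets")
  if (length(query) == 0L)
    return(numeric(0))
  covered <- numeric(length(query))
  hits <- GenomicRanges::findOverlaps(query, targets,
                                      ignore.strand = !strandAware)
  if (length(hits)) {
    q <- query[S4Vectors::queryHits(hits)]
    t <- targets[S4Vectors::subjectHits(hits)]
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(q), GenomicRanges::ranges(t)))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / GenomicRanges::width(query)
}

#' Report query/target interval pairs passing overlap thresholds
#'
#' A pair is reported when the overlap is at least \code{minBp} nucleotides
#' and the fractional thresholds hold: with \code{eitherSuffices = TRUE} the
#' overlap must reach \code{minFracQuery} of the query size \emph{or}
#' \code{minFracTarget} of the target size; with \code{eitherSuffices = FALSE}
#' both.  Strand is ignored.
#'
#' @param queries,targets GRanges
#' @param minFracQuery,minFracTarget fractions in [0, 1]
#' @param eitherSuffices logical, see above
#' @param minBp minimum absolute overlap in nucleotides (>= 1)
#' @return data.frame with columns queryIdx, targetIdx, overlap
#' @export
overlapPairs <- function(queries, targets, minFracQuery = 0,
                         minFracTarget = 0, eitherSuffices = TRUE,
                         minBp = 1L) {
  stopifnot(is(queries, "GRanges"), is(targets, "GRanges"))
  if (minFracQuery < 0 || minFracQuery > 1 || minFracTarget < 0 ||
      minFracTarget > 1)
    .crsStop("fraction thresholds must lie in [0, 1]", "crsValidationError")
  if (minBp < 1)
    .crsStop("minBp must be >= 1", "crsValidationError")
  hits <- GenomicRanges::findOverlaps(queries, targets, minoverlap = minBp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(queries)[qi], GenomicRanges::ranges(targets)[ti]))
  passQ <- ov >= minFracQuery * GenomicRanges::width(queries)[qi]
  passT <- ov >= minFracTarget * GenomicRanges::width(targets)[ti]
  keep <- if (eitherSuffices) passQ | passT else passQ & passT
  data.frame(queryIdx = qi[keep], targetIdx = ti[keep], overlap = ov[keep])
}

#' All closest features to a query interval, with ties
#'
#' Distance is edge-to-edge between intervals (0 when they overlap or touch).
#' All features at the minimum distance are returned, so ties are preserved
#' for downstream consumers.  An empty feature track yields an empty result
#' with zero rows rather than an error.
#'
#' @param query a single-interval GRanges (or one interval per call)
#' @param features a GRanges of candidate features
#' @param ignoreStrand ignored strand when computing distances (default TRUE)
#' @return data.frame with columns featureIdx, distance, side
#'   (upstream = feature left of query in genome coordinates, downstream =
#'   right, overlapping = >= 1 bp shared)
#' @export
closestFeatures <- function(query, features, ignoreStrand = TRUE) {
  stopifnot(is(query, "GRanges"), length(query) == 1L, is(features, "GRanges"))
  empty <- data.frame(featureIdx = integer(0), distance = numeric(0),
                      side = character(0))
  if (length(features) == 0L)
    return(empty)
  qs <- GenomicRanges::start(query)
  qe <- GenomicRanges::end(query)
  fs <- GenomicRanges::start(features)
  fe <- GenomicRanges::end(features)
  ## edge-to-edge gap between closed intervals; 0 when touching/overlapping
  d <- pmax(0L, pmax(fs - qe - 1L, qs - fe - 1L))
  d[as.character(GenomeInfoDb::seqnames(features)) !=
      as.character(GenomeInfoDb::seqnames(query))] <- NA
  if (all(is.na(d)))
    return(empty)
  idx <- which(!is.na(d) & d == min(d, na.rm = TRUE))
  ov <- fs[idx] <= qe & fe[idx] >= qs
  side <- ifelse(ov, "overlapping",
                 ifelse(fe[idx] <= qs, "upstream", "downstream"))
  data.frame(featureIdx = idx, distance = d[idx], side = side)
}

## validate that a GRanges is a well-formed track (positive widths are
## enforced by GRanges itself); flags which record failed
validateTrack <- function(track, what = "track") {
  if (!is(track, "GRanges"))
    .crsStop(sprintf("%s must be a GRanges", what), "crsValidationError")
  invisible(track)
}
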