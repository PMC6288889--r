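#' Synteny tests for co-expressed CRS-gene pairs
#'
#' For each CRS-gene pair, evaluates three criteria in every companion
#' species with an available ortholog:
#' \describe{
#'   \item{strict}{the ortholog of the focal gene is (one of) the closest
#'     gene(s) to the CRS in the species;}
#'   \item{orientation}{the ortholog, wherever it lies, is on the same side
#'     (upstream/downstream) of the CRS as the focal gene;}
#'   \item{distance}{orientation holds and both the focal pair and the
#'     species pair are separated by at most \code{maxDistance} nt.}
#' }
#' A criterion passes in aggregate when it is satisfied in at least
#' \code{requiredFraction} of the species with an available ortholog
#' (ceiling).  With tied closest genes, one tie member satisfying the
#' criterion suffices.  Species lacking the ortholog are excluded from the
#' denominator.
#'
#' @param pairs data.frame(crs_id, gene_id) of focal pairs
#' @param focalCrs GRanges of focal CRS loci with \code{id}
#' @param focalGenes GRanges of focal gene spans with \code{ID}
#' @param orthologs data.frame(gene_id, species, ortholog_id)
#' @param speciesGenes named list (per species) of GRanges with \code{id}
#' @param speciesCrs named list (per species) of GRanges with \code{id}
#' @param requiredFraction species fraction per criterion (default 2/3)
#' @param maxDistance distance cutoff in nt (default 20000)
#' @return list(verdicts = data.frame(crs_id, gene_id, n_species, strict,
#'   orientation, distance), perSpecies = data.frame of per-species flags)
#' @export
syntenyTests <- function(pairs, focalCrs, focalGenes, orthologs,
                         speciesGenes, speciesCrs, requiredFraction = 2 / 3,
                         maxDistance = 20000L) {
  stopifnot(is.data.frame(pairs), is.data.frame(orthologs))
  perSpecies <- list()
  verdicts <- list()
  for (k in seq_len(nrow(pairs))) {
    crsId <- pairs$crs_id[k]
    geneId <- pairs$gene_id[k]
    fc <- focalCrs[focalCrs$id == crsId]
    fg <- focalGenes[focalGenes$ID == geneId]
    if (length(fc) != 1L || length(fg) != 1L)
      .crsStop(sprintf("pair %s/%s not found in focal annotation", crsId,
                       geneId), "crsValidationError")
    focalSide <- .sideOf(fc, fg)
    focalDist <- GenomicRanges::distance(fc, fg, ignore.strand = TRUE)
    flags <- list()
    for (sp in names(speciesGenes)) {
      orthId <- orthologs$ortholog_id[orthologs$gene_id == geneId &
                                        orthologs$species == sp]
      sg <- speciesGenes[[sp]]
      sc <- speciesCrs[[sp]][speciesCrs[[sp]]$id == crsId]
      if (length(orthId) == 0L || length(sc) != 1L ||
          !any(sg$id %in% orthId)) {
        message(sprintf("pair %s/%s: no ortholog in %s; species excluded",
                        crsId, geneId, sp))
        next
      }
      orth <- sg[sg$id %in% orthId]
      closest <- closestFeatures(sc, sg)
      closestIds <- sg$id[closest$featureIdx]
      strict <- any(orthId %in% closestIds)
      ## one tie member (ortholog copy) on the focal side suffices
      orientation <- any(vapply(seq_along(orth), function(j)
        .sideOf(sc, orth[j]) == focalSide, logical(1)))
      dists <- GenomicRanges::distance(
        sc, orth, ignore.strand = TRUE)
      distanceOk <- orientation && focalDist <= maxDistance &&
        any(vapply(seq_along(orth), function(j)
          .sideOf(sc, orth[j]) == focalSide && dists[j] <= maxDistance,
          logical(1)))
      flags[[length(flags) + 1L]] <- data.frame(
        crs_id = crsId, gene_id = geneId, species = sp, strict = strict,
        orientation = orientation, distance = distanceOk)
    }
    fl <- if (length(flags)) do.call(rbind, flags) else NULL
    nSp <- if (is.null(fl)) 0L else nrow(fl)
    need <- ceiling(requiredFraction * nSp)
    agg <- function(col) nSp > 0L && sum(fl[[col]]) >= need
    verdicts[[length(verdicts) + 1L]] <- data.frame(
      crs_id = crsId, gene_id = geneId, n_species = nSp,
      strict = agg("strict"), orientation = agg("orientation"),
      distance = agg("distance"))
    if (!is.null(fl)) perSpecies[[length(perSpecies) + 1L]] <- fl
  }
  list(verdicts = do.call(rbind, verdicts),
       perSpecies = if (length(perSpecies)) do.call(rbind, perSpecies) else
         NULL)
}

## which side of the query does the feature lie on (midpoint rule for
## overlaps, which do not occur for intergenic CRSs vs gene spans)
.sideOf <- function(query, feature) {
  if (GenomicRanges::end(feature) <= GenomicRanges::start(query))
    "upstream"
  else if (GenomicRanges::start(feature) >= GenomicRanges::end(query))
    "downstream"
  else "overlapping"
}
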