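#' Input filter for alignment blocks
#'
#' Removes alignment blocks shorter than 50 bp or containing fewer than three
#' sequences; only blocks passing this filter were fed to the motif finder,
#' so all downstream counting is restricted to them.
#'
#' @param blocks GRanges with an \code{n_species} metadata column
#' @param minLength minimum block length in nt (default 50, inclusive)
#' @param minSpecies minimum species count (default 3, inclusive)
#' @return the retained blocks
#' @export
filterInputBlocks <- function(blocks, minLength = 50L, minSpecies = 3L) {
  validateTrack(blocks, "blocks")
  if (length(blocks) == 0L) return(blocks)
  if (is.null(blocks$n_species))
    .crsStop("blocks need an 'n_species' metadata column",
             "crsValidationError")
  blocks[GenomicRanges::width(blocks) >= minLength &
           blocks$n_species >= minSpecies]
}

#' Filter motifs by pscore
#'
#' Retains motifs with pscore strictly greater than the cutoff.
#'
#' @param motifs motif GRanges with a \code{pscore} column
#' @param cutoff finite numeric cutoff (strict >)
#' @export
filterPscore <- function(motifs, cutoff) {
  validateTrack(motifs, "motifs")
  stopifnot(length(cutoff) == 1L, !is.na(cutoff))
  motifs[motifs$pscore > cutoff]
}

#' Remove motifs lying mostly in repeats
#'
#' A motif is removed when at least \code{minFrac} of its length overlaps the
#' (merged) repeat track; alignments are unreliable in repetitive regions.
#'
#' @param motifs motif GRanges
#' @param repeats merged repeat GRanges
#' @param minFrac removal threshold on the covered fraction (default 0.5,
#'   inclusive)
#' @return list(motifs = retained GRanges, removed = count removed)
#' @export
filterRepeatOverlap <- function(motifs, repeats, minFrac = 0.5) {
  validateTrack(motifs, "motifs")
  if (length(motifs) == 0L || length(repeats) == 0L)
    return(list(motifs = motifs, removed = 0L))
  frac <- coverageFraction(motifs, repeats)
  drop <- frac >= minFrac
  list(motifs = motifs[!drop], removed = sum(drop))
}

#' Build a marginal-quantile bin grid from native motifs
#'
#' Edges are marginal quantiles of the native motifs' GC content and sequence
#' identity, so each bin holds a comparable number of predictions; blocks and
#' shuffled motifs are mapped onto the same edges.  Degenerate dimensions
#' (ties collapsing quantiles) reduce the effective bin count with a warning.
#'
#' @param motifs native motif GRanges (columns gc, identity)
#' @param nGcBins,nIdentityBins requested bin counts (default 8 x 8)
#' @return a [BinGrid-class]
#' @export
buildBins <- function(motifs, nGcBins = 8L, nIdentityBins = 8L) {
  validateTrack(motifs, "motifs")
  if (length(motifs) < nGcBins * nIdentityBins)
    .crsStop(sprintf(paste("only %d motifs for %d requested bins; use fewer",
                           "bins"), length(motifs), nGcBins * nIdentityBins),
             "crsTooFewMotifs")
  mkEdges <- function(x, n, what) {
    e <- unname(quantile(x, probs = seq(0, 1, length.out = n + 1L)))
    e <- unique(e)
    if (length(e) < 2L) {
      warning(sprintf("all motifs have identical %s; single bin used", what))
      e <- c(e, e + 1e-9)
    } else if (length(e) < n + 1L) {
      warning(sprintf("quantile ties reduced %s bins to %d", what,
                      length(e) - 1L))
    }
    e
  }
  new("BinGrid", gcEdges = mkEdges(motifs$gc, nGcBins, "GC"),
      identityEdges = mkEdges(motifs$identity, nIdentityBins, "identity"))
}

#' Map GC/identity values to bin indices of a grid
#'
#' Values outside the edge range are clamped to the first/last bin.
#'
#' @param grid a [BinGrid-class]
#' @param gc,identity numeric vectors
#' @return data.frame(gc_bin, id_bin)
#' @export
binIndex <- function(grid, gc, identity) {
  stopifnot(is(grid, "BinGrid"))
  nb <- nBins(grid)
  gi <- .clamp(findInterval(gc, grid@gcEdges, rightmost.closed = TRUE),
               1L, nb[["gc"]])
  ii <- .clamp(findInterval(identity, grid@identityEdges,
                            rightmost.closed = TRUE), 1L, nb[["identity"]])
  data.frame(gc_bin = gi, id_bin = ii)
}

#' Estimate the binned false discovery rate
#'
#' For every (GC bin, identity bin, pscore cutoff) cell, counts native and
#' shuffled predictions with pscore strictly greater than the cutoff and
#' estimates FDR = shuffled/native, capped at 1 (NA when no native
#' predictions).  Bins holding fewer than \code{minBlocks} alignment blocks
#' are flagged low-reliability.
#'
#' @param native,shuffled motif GRanges (repeat-filtered)
#' @param blocks filtered input blocks (GRanges with gc, identity)
#' @param grid a [BinGrid-class] built on the native motifs
#' @param cutoffs ascending pscore cutoffs; default scans 50 to 150
#' @param minBlocks reliability threshold on per-bin block counts
#' @return an [FdrTable-class]
#' @export
estimateFdr <- function(native, shuffled, blocks, grid,
                        cutoffs = seq(50, 150, by = 10), minBlocks = 100L) {
  stopifnot(is(grid, "BinGrid"))
  if (is.unsorted(cutoffs, strictly = TRUE))
    .crsStop("cutoffs must be ascending", "crsValidationError")
  if (length(native) == 0L)
    warning("no native predictions: all FDR estimates undefined")
  nb <- nBins(grid)
  countBy <- function(gr, cutoff) {
    if (length(gr) == 0L)
      return(matrix(0L, nb[["gc"]], nb[["identity"]]))
    keep <- gr$pscore > cutoff
    b <- binIndex(grid, gr$gc[keep], gr$identity[keep])
    as.matrix(table(factor(b$gc_bin, levels = seq_len(nb[["gc"]])),
                    factor(b$id_bin, levels = seq_len(nb[["identity"]]))))
  }
  bb <- if (length(blocks)) binIndex(grid, blocks$gc, blocks$identity) else
    data.frame(gc_bin = integer(0), id_bin = integer(0))
  blockCounts <- as.matrix(table(
    factor(bb$gc_bin, levels = seq_len(nb[["gc"]])),
    factor(bb$id_bin, levels = seq_len(nb[["identity"]]))))
  out <- do.call(rbind, lapply(cutoffs, function(ct) {
    natM <- countBy(native, ct)
    shufM <- countBy(shuffled, ct)
    idx <- expand.grid(gc_bin = seq_len(nb[["gc"]]),
                       id_bin = seq_len(nb[["identity"]]))
    nat <- natM[cbind(idx$gc_bin, idx$id_bin)]
    shuf <- shufM[cbind(idx$gc_bin, idx$id_bin)]
    data.frame(gc_bin = idx$gc_bin, id_bin = idx$id_bin, cutoff = ct,
               native = nat, shuffled = shuf,
               fdr = ifelse(nat > 0, pmin(1, shuf / nat), NA_real_),
               n_blocks = blockCounts[cbind(idx$gc_bin, idx$id_bin)])
  }))
  out$low_reliability <- out$n_blocks < minBlocks
  rownames(out) <- NULL
  new("FdrTable", table = out, grid = grid, cutoffs = as.numeric(cutoffs),
      minBlocks = as.numeric(minBlocks))
}

#' Select high-confidence motifs by pscore and bin FDR
#'
#' A motif is retained when its pscore strictly exceeds \code{pscoreMin} and
#' the FDR of its (GC, identity) bin at the \code{pscoreMin} cutoff is at
#' most \code{fdrMax}.  Retained motifs carry their bin FDR in an \code{fdr}
#' metadata column.  Motifs in bins with undefined FDR are excluded
#' (conservative) and their count reported; motifs outside the grid range are
#' clamped to edge bins.
#'
#' @param motifs native motif GRanges
#' @param fdrTab an [FdrTable-class] whose cutoffs include \code{pscoreMin}
#' @param pscoreMin pscore gate (default 80, strict >)
#' @param fdrMax FDR gate (default 0.1, inclusive)
#' @return list(motifs = selected GRanges with fdr column,
#'   excluded_undefined = count of motifs in undefined-FDR bins)
#' @export
selectCrsMotifs <- function(motifs, fdrTab, pscoreMin = 80, fdrMax = 0.1) {
  stopifnot(is(fdrTab, "FdrTable"))
  if (!pscoreMin %in% fdrTab@cutoffs)
    .crsStop(sprintf("pscoreMin %s is not among the FDR table cutoffs",
                     pscoreMin), "crsValidationError")
  tab <- fdrTab@table[fdrTab@table$cutoff == pscoreMin, ]
  nb <- nBins(fdrTab@grid)
  fdrM <- matrix(NA_real_, nb[["gc"]], nb[["identity"]])
  fdrM[cbind(tab$gc_bin, tab$id_bin)] <- tab$fdr
  b <- binIndex(fdrTab@grid, motifs$gc, motifs$identity)
  motifs$fdr <- fdrM[cbind(b$gc_bin, b$id_bin)]
  motifs$gc_bin <- b$gc_bin
  motifs$id_bin <- b$id_bin
  passP <- motifs$pscore > pscoreMin
  undef <- passP & is.na(motifs$fdr)
  keep <- passP & !is.na(motifs$fdr) & motifs$fdr <= fdrMax
  if (any(undef))
    message(sum(undef), " motif(s) in bins with undefined FDR excluded")
  list(motifs = motifs[keep], excluded_undefined = sum(undef))
}
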