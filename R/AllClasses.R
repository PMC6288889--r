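#' Quantile bin grid over GC content and sequence identity
#'
#' A \code{BinGrid} stores the cut points that partition motif predictions (and
#' alignment blocks) into bins of GC content and mean pairwise sequence
#' identity.  Bins are built so that each contains a comparable number of
#' native predictions; blocks and shuffled predictions are mapped onto the same
#' edges.  Values outside the edge range are clamped to the first/last bin.
#'
#' @slot gcEdges ascending numeric cut points on [0, 1] for GC content
#' @slot identityEdges ascending numeric cut points on [0, 1] for identity
#'
#' @seealso [buildBins()], [binIndex()], [estimateFdr()]
#' @export
setClass("BinGrid",
         representation(gcEdges = "numeric", identityEdges = "numeric"))

setValidity("BinGrid", function(object) {
  msg <- character()
  for (nm in c("gcEdges", "identityEdges")) {
    e <- slot(object, nm)
    if (length(e) < 2L)
      msg <- c(msg, paste0(nm, " needs at least 2 edges"))
    else if (any(diff(e) <= 0))
      msg <- c(msg, paste0(nm, " must be strictly increasing"))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BinGrid number of (GC, identity) bins as c(gc, identity)
#' @param x,object a \code{BinGrid}
#' @export
nBins <- function(x) {
  stopifnot(is(x, "BinGrid"))
  c(gc = length(x@gcEdges) - 1L, identity = length(x@identityEdges) - 1L)
}

setMethod("show", "BinGrid", function(object) {
  nb <- nBins(object)
  cat("BinGrid: ", nb[["gc"]], " GC bins x ", nb[["identity"]],
      " identity bins\n", sep = "")
  cat("  gc edges:       ", paste(signif(object@gcEdges, 3), collapse = " "),
      "\n")
  cat("  identity edges: ",
      paste(signif(object@identityEdges, 3), collapse = " "), "\n")
})

#' Binned false discovery rate table
#'
#' Per (GC bin, identity bin, pscore cutoff) cell: the number of native and
#' shuffled predictions exceeding the cutoff, the FDR estimate
#' shuffled/native capped at 1 (NA when the native count is zero), and the
#' number of alignment blocks falling in the bin.  Bins with fewer than
#' \code{minBlocks} blocks are flagged low-reliability.
#'
#' @slot table data.frame with columns gc_bin, id_bin, cutoff, native,
#'   shuffled, fdr, n_blocks, low_reliability
#' @slot grid the [BinGrid-class] the table was computed on
#' @slot cutoffs ascending numeric pscore cutoffs scanned
#' @slot minBlocks block-count threshold below which a bin is flagged
#'
#' @seealso [estimateFdr()], [selectCrsMotifs()]
#' @export
setClass("FdrTable",
         representation(table = "data.frame", grid = "BinGrid",
                        cutoffs = "numeric", minBlocks = "numeric"))

setValidity("FdrTable", function(object) {
  need <- c("gc_bin", "id_bin", "cutoff", "native", "shuffled", "fdr",
            "n_blocks", "low_reliability")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  f <- object@table$fdr
  if (any(!is.na(f) & (f < 0 | f > 1)))
    return("fdr estimates must lie in [0, 1] or be NA")
  if (is.unsorted(object@cutoffs, strictly = TRUE))
    return("cutoffs must be strictly ascending")
  TRUE
})

#' @describeIn FdrTable the underlying per-cell data.frame
#' @param x,object an \code{FdrTable}
#' @export
fdrTable <- function(x) {
  stopifnot(is(x, "FdrTable"))
  x@table
}

setMethod("show", "FdrTable", function(object) {
  nb <- nBins(object@grid)
  cat("FdrTable: ", nb[["gc"]], " x ", nb[["identity"]], " bins, ",
      length(object@cutoffs), " pscore cutoffs (",
      min(object@cutoffs), "..", max(object@cutoffs), ")\n", sep = "")
  defined <- !is.na(object@table$fdr)
  cat("  cells: ", nrow(object@table), " (", sum(defined),
      " with defined FDR)\n", sep = "")
  if (any(defined))
    cat("  FDR range: ",
        paste(signif(range(object@table$fdr[defined]), 3), collapse = " .. "),
        "\n", sep = "")
})

#' Single-label unified genome annotation
#'
#' A non-overlapping partition of every annotated chromosome into segments,
#' each carrying exactly one category: \code{coding_exon}, \code{utr5_exon},
#' \code{utr3_exon}, \code{both_utr_exon}, \code{ncrna_exon}, \code{intron}, or
#' \code{intergenic}.  Strand is ignored throughout.  Validity enforces the
#' partition property: segments are disjoint, sorted, and their widths sum to
#' the chromosome length recorded in the seqinfo.
#'
#' @slot segments an unstranded, sorted, disjoint [GenomicRanges::GRanges] with
#'   a \code{category} factor metadata column and seqlengths set
#'
#' @seealso [unifyAnnotation()], [assignFractionalCategories()]
#' @export
setClass("UnifiedAnnotation", representation(segments = "GRanges"))

.annotationCategories <- c("coding_exon", "utr5_exon", "utr3_exon",
                           "both_utr_exon", "ncrna_exon", "intron",
                           "intergenic")

setValidity("UnifiedAnnotation", function(object) {
  gr <- object@segments
  if (is.null(gr$category))
    return("segments need a 'category' metadata column")
  if (!all(as.character(gr$category) %in% .annotationCategories))
    return("unknown annotation category")
  if (!all(GenomicRanges::strand(gr) == "*"))
    return("segments must be unstranded")
  if (!IRanges::isDisjoint(gr))
    return("segments must be disjoint")
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl)))
    return("seqlengths must be set for all chromosomes")
  covered <- sum(GenomicRanges::width(gr))
  if (covered != sum(as.numeric(sl)))
    return(sprintf("segments cover %d nt but chromosomes total %d nt",
                   covered, sum(as.numeric(sl))))
  TRUE
})

#' @describeIn UnifiedAnnotation the segment GRanges (category in mcols)
#' @param x,object a \code{UnifiedAnnotation}
#' @export
annotationSegments <- function(x) {
  stopifnot(is(x, "UnifiedAnnotation"))
  x@segments
}

#' @describeIn UnifiedAnnotation total nt per category
#' @export
categorySizes <- function(x) {
  gr <- annotationSegments(x)
  vapply(split(GenomicRanges::width(gr), gr$category), sum, numeric(1))
}

setMethod("show", "UnifiedAnnotation", function(object) {
  gr <- object@segments
  cat("UnifiedAnnotation:", length(gr), "segments on",
      length(GenomeInfoDb::seqlevels(gr)), "chromosome(s)\n")
  sz <- categorySizes(object)
  pct <- 100 * sz / sum(sz)
  for (i in seq_along(sz))
    cat(sprintf("  %-14s %10d nt (%5.1f%%)\n", names(sz)[i], sz[i], pct[i]))
})
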