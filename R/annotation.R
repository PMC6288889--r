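#' Unify gene models and ncRNA features into a single-label annotation
#'
#' Produces a partition of every chromosome in which each nucleotide carries
#' exactly one category.  Priorities: a position inside an exon and inside
#' merged coding sequence is a coding exon; an ncRNA exon or ncRNA feature
#' overrides UTR labels; positions where 5'- and 3'-UTR exons overlap become
#' "both UTRs"; remaining exonic UTR positions take their single UTR label;
#' gene-span positions not in any exon are introns; everything else is
#' intergenic.  Strand is ignored throughout (UTR sidedness is resolved per
#' gene from its strand before strands are dropped).
#'
#' @param geneModels GRanges of gene/exon/CDS rows with ID/Parent links, as
#'   from [readGeneModels()] or [simulateGenome()]; seqlengths must be set
#' @param ncrnaFeatures GRanges of annotated ncRNA features (may be empty)
#' @return a [UnifiedAnnotation-class]
#' @export
unifyAnnotation <- function(geneModels, ncrnaFeatures =
                              GenomicRanges::GRanges()) {
  validateTrack(geneModels, "geneModels")
  sl <- GenomeInfoDb::seqlengths(geneModels)
  if (length(sl) == 0L || any(is.na(sl)))
    .crsStop("geneModels must carry seqlengths for every chromosome",
             "crsValidationError")
  genes <- geneModels[geneModels$type == "gene"]
  exons <- geneModels[geneModels$type == "exon"]
  cds <- geneModels[geneModels$type == "CDS"]
  if (length(exons) && (is.null(exons$Parent) || anyNA(exons$Parent)))
    .crsStop("exon without parent gene", "crsValidationError")

  un <- function(gr) GenomicRanges::reduce(BiocGenerics::unstrand(gr))
  cdsM <- un(cds)
  codingGenes <- unique(cds$Parent)
  codingExons <- GenomicRanges::intersect(un(exons), cdsM)

  ## UTR parts of coding genes, sided by the owning gene's strand
  u <- .utrParts(geneModels)
  utr5 <- un(u$utr5)
  utr3 <- un(u$utr3)

  ncExons <- exons[!(exons$Parent %in% codingGenes)]
  ncrna <- un(c(GenomicRanges::granges(ncExons),
                GenomicRanges::granges(ncrnaFeatures)))

  sd <- function(a, b) GenomicRanges::setdiff(a, b)
  coding <- codingExons
  ncrnaSeg <- sd(ncrna, coding)
  taken <- un(c(coding, ncrnaSeg))
  bothUtr <- sd(GenomicRanges::intersect(utr5, utr3), taken)
  taken <- un(c(taken, bothUtr))
  utr5Seg <- sd(sd(utr5, utr3), taken)
  utr3Seg <- sd(sd(utr3, utr5), taken)
  exonic <- un(c(coding, ncrnaSeg, bothUtr, utr5Seg, utr3Seg))
  geneSpan <- un(GenomicRanges::granges(genes))
  introns <- sd(geneSpan, exonic)
  genome <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl),
                                   seqlengths = sl)
  intergenic <- sd(genome, un(c(geneSpan, exonic)))

  lab <- function(gr, category) {
    if (length(gr)) gr$category <- category
    gr
  }
  seg <- c(lab(coding, "coding_exon"), lab(ncrnaSeg, "ncrna_exon"),
           lab(bothUtr, "both_utr_exon"), lab(utr5Seg, "utr5_exon"),
           lab(utr3Seg, "utr3_exon"), lab(introns, "intron"),
           lab(intergenic, "intergenic"))
  seg$category <- factor(seg$category, levels = .annotationCategories)
  seg <- BiocGenerics::sort(seg)
  new("UnifiedAnnotation", segments = seg)
}

#' Fractional category assignment of loci
#'
#' Each locus contributes a total weight of 1, split equally among the
#' distinct unified annotation elements it overlaps by at least 1 bp (a locus
#' overlapping an intron element and a coding-exon element adds 0.5 to each;
#' one overlapping two intron elements and one intergenic element adds 2/3
#' and 1/3).  Loci on chromosomes absent from the annotation are counted as
#' "unmapped".  Counts are kept as exact fractions; rounding happens only at
#' report time.
#'
#' @param loci unstranded GRanges of CRS loci
#' @param unified a [UnifiedAnnotation-class]
#' @return data.frame(category, count, percentage); counts sum to
#'   \code{length(loci)} exactly
#' @export
assignFractionalCategories <- function(loci, unified) {
  stopifnot(is(unified, "UnifiedAnnotation"))
  seg <- annotationSegments(unified)
  cats <- c(.annotationCategories, "unmapped")
  counts <- setNames(numeric(length(cats)), cats)
  if (length(loci)) {
    mapped <- as.character(GenomeInfoDb::seqnames(loci)) %in%
      GenomeInfoDb::seqlevels(seg)
    counts[["unmapped"]] <- sum(!mapped)
    hits <- GenomicRanges::findOverlaps(loci[mapped], seg,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    perLocus <- table(qh)
    w <- 1 / as.numeric(perLocus[as.character(qh)])
    cat <- as.character(seg$category[S4Vectors::subjectHits(hits)])
    agg <- tapply(w, cat, sum)
    counts[names(agg)] <- as.numeric(agg)
  }
  data.frame(category = cats, count = as.numeric(counts),
             percentage = if (length(loci))
               100 * as.numeric(counts) / length(loci) else 0,
             row.names = NULL)
}

#' Fold enrichment of overlap counts against a genomic background
#'
#' FE = (nOverlap/nQueries) / (targetSize/backgroundSize): the fraction of
#' queries hitting the target class, relative to the fraction of the screened
#' background the class occupies.
#'
#' @param nOverlap number (possibly fractional) of queries overlapping the
#'   target class
#' @param nQueries total queries
#' @param targetSize nt of the target class within the screened input
#' @param backgroundSize total nt of the screened input
#' @return numeric fold enrichment (NA with a warning if targetSize is 0)
#' @export
foldEnrichment <- function(nOverlap, nQueries, targetSize, backgroundSize) {
  if (any(targetSize <= 0)) {
    warning("targetSize is 0: fold enrichment undefined")
    return(ifelse(targetSize > 0,
                  (nOverlap / nQueries) / (targetSize / backgroundSize),
                  NA_real_))
  }
  stopifnot(nQueries > 0, backgroundSize > 0, all(nOverlap >= 0))
  (nOverlap / nQueries) / (targetSize / backgroundSize)
}

#' Normal-approximation enrichment p-value
#'
#' One-sided p-value for the observed overlap count under a binomial null:
#' with n queries and target fraction f, mean = n f and sd = sqrt(n f (1-f)).
#' Upper tail when the observation exceeds the mean, lower tail otherwise
#' (an observation exactly at the mean gives 0.5).
#'
#' @param nOverlap observed overlap count
#' @param nQueries number of queries
#' @param targetFraction fraction of the background covered by the target,
#'   in (0, 1)
#' @return one-sided p-value (NA with a warning when the sd is 0)
#' @export
enrichmentPvalue <- function(nOverlap, nQueries, targetFraction) {
  bad <- targetFraction <= 0 | targetFraction >= 1
  if (any(bad))
    warning("degenerate target fraction: p-value undefined for ",
            sum(bad), " entr(y/ies)")
  f <- ifelse(bad, NA_real_, targetFraction)
  mu <- nQueries * f
  sigma <- sqrt(nQueries * f * (1 - f))
  ifelse(nOverlap >= mu,
         pnorm(nOverlap, mu, sigma, lower.tail = FALSE),
         pnorm(nOverlap, mu, sigma, lower.tail = TRUE))
}

#' Filter annotated ncRNA features for recoverability
#'
#' Retains features that are structured (base-pair content >= 0.3), lie at
#' least half inside the screen's input alignment blocks, and overlap repeats
#' by strictly less than half their size.
#'
#' @param features ncRNA GRanges with a \code{bp_content} column
#' @param blocks merged input-block GRanges
#' @param repeats merged repeat GRanges
#' @param minBpContent base-pair-content threshold (default 0.3, inclusive)
#' @return the retained features
#' @export
filterNcrnaFeatures <- function(features, blocks, repeats,
                                minBpContent = 0.3) {
  validateTrack(features, "features")
  if (length(features) == 0L) return(features)
  inBlocks <- coverageFraction(features, mergeTrack(blocks))
  inReps <- if (length(repeats))
    coverageFraction(features, mergeTrack(repeats)) else
      numeric(length(features))
  features[features$bp_content >= minBpContent & inBlocks >= 0.5 &
             inReps < 0.5]
}

#' Recovery of annotated ncRNA classes by the screen
#'
#' A feature counts as overlapped when some locus covers at least 50% of the
#' locus or of the feature (either side suffices).  One row per ncRNA class
#' plus an "All" row: filtered feature count, features overlapped, percentage
#' of filtered features overlapped, and the number of distinct loci matched.
#'
#' @param loci CRS locus GRanges
#' @param features filtered ncRNA GRanges with a \code{class} column
#' @param minFrac the either-side overlap fraction (default 0.5)
#' @return data.frame(class, n_filtered, n_overlapped, percentage, n_crs);
#'   percentage is NA when a class has no filtered features
#' @export
ncrnaRecoveryTable <- function(loci, features, minFrac = 0.5) {
  pairs <- overlapPairs(loci, features, minFracQuery = minFrac,
                        minFracTarget = minFrac, eitherSuffices = TRUE)
  classes <- sort(unique(features$class))
  rows <- lapply(c(classes, "All"), function(cl) {
    idx <- if (cl == "All") seq_along(features) else
      which(features$class == cl)
    hit <- pairs[pairs$targetIdx %in% idx, ]
    nf <- length(idx)
    no <- length(unique(hit$targetIdx))
    data.frame(class = cl, n_filtered = nf, n_overlapped = no,
               percentage = if (nf > 0) 100 * no / nf else NA_real_,
               n_crs = length(unique(hit$queryIdx)))
  })
  do.call(rbind, rows)
}

#' Per-category enrichment of loci in the unified annotation
#'
#' Combines [assignFractionalCategories()], [foldEnrichment()] and
#' [enrichmentPvalue()].  The target size of a category is the total length
#' of its elements that overlap an input block by at least 1 nt; the
#' background size is the total length of the input blocks.
#'
#' @param loci CRS locus GRanges
#' @param unified a [UnifiedAnnotation-class]
#' @param blocks filtered input-block GRanges
#' @return data.frame(category, count, percentage, target_size,
#'   fold_enrichment, p_value)
#' @export
annotationEnrichmentTable <- function(loci, unified, blocks) {
  frac <- assignFractionalCategories(loci, unified)
  seg <- annotationSegments(unified)
  blocksM <- mergeTrack(blocks)
  background <- sum(as.numeric(GenomicRanges::width(blocks)))
  inBlock <- IRanges::overlapsAny(seg, blocksM, ignore.strand = TRUE)
  tsz <- vapply(split(GenomicRanges::width(seg)[inBlock],
                      seg$category[inBlock]), sum, numeric(1))
  frac$target_size <- as.numeric(tsz[frac$category])
  frac$target_size[is.na(frac$target_size)] <- 0
  n <- sum(frac$count)
  fe <- p <- rep(NA_real_, nrow(frac))
  ok <- frac$category != "unmapped" & frac$target_size > 0
  fe[ok] <- foldEnrichment(frac$count[ok], n, frac$target_size[ok],
                           background)
  f <- frac$target_size[ok] / background
  p[ok] <- enrichmentPvalue(frac$count[ok], n, f)
  frac$fold_enrichment <- fe
  frac$p_value <- p
  frac
}

## UTR exon parts of coding genes: each exon is clipped against its own
## gene's CDS span (min CDS start to max CDS end), so overlapping genes are
## handled per gene.  Parts left of the span are 5' on + genes and 3' on -
## genes, and conversely on the right.  Internal non-CDS exon pieces inside
## the span are not UTRs.
.utrParts <- function(geneModels) {
  genes <- geneModels[geneModels$type == "gene"]
  exons <- geneModels[geneModels$type == "exon"]
  cds <- geneModels[geneModels$type == "CDS"]
  codingGenes <- unique(cds$Parent)
  empty <- GenomicRanges::GRanges(
    seqinfo = GenomeInfoDb::seqinfo(geneModels))
  none <- list(utr5 = empty, utr3 = empty, parts = empty,
               gene = character(0), partIs5 = logical(0),
               partIs3 = logical(0))
  if (!length(codingGenes))
    return(none)
  codingEx <- exons[exons$Parent %in% codingGenes]
  if (!length(codingEx))
    return(none)
  cdsFrom <- tapply(GenomicRanges::start(cds), cds$Parent, min)
  cdsTo <- tapply(GenomicRanges::end(cds), cds$Parent, max)
  strandOf <- setNames(as.character(GenomicRanges::strand(genes)),
                       genes$ID)
  p <- as.character(codingEx$Parent)
  exSt <- GenomicRanges::start(codingEx)
  exEn <- GenomicRanges::end(codingEx)
  cf <- as.numeric(cdsFrom[p])
  ct <- as.numeric(cdsTo[p])
  minus <- strandOf[p] == "-"
  chr <- as.character(GenomeInfoDb::seqnames(codingEx))
  clip <- function(lo, hi) {
    keep <- which(hi >= lo)
    g <- GenomicRanges::GRanges(chr[keep],
                                IRanges::IRanges(lo[keep], hi[keep]),
                                seqinfo = GenomeInfoDb::seqinfo(geneModels))
    list(gr = g, idx = keep)
  }
  left <- clip(exSt, pmin(exEn, cf - 1))
  right <- clip(pmax(exSt, ct + 1), exEn)
  parts <- c(left$gr, right$gr)
  gene <- c(p[left$idx], p[right$idx])
  onLeft <- c(rep(TRUE, length(left$idx)), rep(FALSE, length(right$idx)))
  mnu <- c(minus[left$idx], minus[right$idx])
  is5 <- (onLeft & !mnu) | (!onLeft & mnu)
  list(utr5 = parts[is5], utr3 = parts[!is5], parts = parts, gene = gene,
       partIs5 = is5, partIs3 = !is5)
}
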