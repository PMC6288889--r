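#' Co-expression score of a CRS with its closest gene element
#'
#' E_co = E_cg/E_c - E_gnc/E_nc: the fraction of CRS-expressing experiments
#' in which the gene element is also expressed (Ratio 1) minus the fraction
#' of CRS-silent experiments in which the gene element is expressed
#' (Ratio 2).  +1 is perfect positive co-expression, -1 perfect negative,
#' 0 independence.  When the CRS is expressed in every experiment
#' (E_nc = 0), Ratio 2 is defined as 0: the gene is never observed without
#' the CRS, which is exactly what Ratio 2 measures.
#'
#' @param eCg experiments with both CRS and gene element expressed
#' @param eC experiments with the CRS expressed (> 0)
#' @param eGnc experiments with the gene element but not the CRS expressed
#' @param eNc experiments without CRS expression
#' @return numeric score in [-1, 1]; vectorized
#' @export
coexpressionScore <- function(eCg, eC, eGnc, eNc) {
  if (any(c(eCg, eC, eGnc, eNc) < 0) || any(eCg > eC) || any(eGnc > eNc))
    .crsStop("invalid experiment counts (need eCg <= eC, eGnc <= eNc, >= 0)",
             "crsValidationError")
  if (any(eC == 0))
    .crsStop("eC must be positive (callers filter at >= 3 expressed)",
             "crsValidationError")
  eCg / eC - ifelse(eNc == 0, 0, eGnc / eNc)
}

#' Co-expression of intergenic CRS loci with their closest gene elements
#'
#' For every intergenic locus expressed in at least \code{minExpr}
#' experiments, finds the closest annotated gene element (UTR exon or ncRNA
#' exon; distance unrestricted), computes the co-expression score from the
#' boolean expression matrix, and classifies it: positive (>= posCut),
#' negative (<= negCut), otherwise independent.  Ties in the closest element
#' produce one record per tied element, flagged.
#'
#' @param loci intergenic CRS GRanges with \code{id}
#' @param geneElements GRanges of UTR/ncRNA exons with \code{id} (element)
#'   and \code{gene_id} columns
#' @param se expression container from [buildExpressionMatrix()] holding
#'   rows for both loci and gene elements
#' @param minExpr minimum CRS-expressing experiments (default 3, inclusive)
#' @param posCut,negCut classification cutoffs (default +/- 0.5, inclusive)
#' @return data.frame(crs_id, element_id, gene_id, distance, side, tie,
#'   e_cg, e_c, e_gnc, e_nc, score, class); class is "no_neighbor" when no
#'   element shares the chromosome
#' @export
computeCoexpression <- function(loci, geneElements, se, minExpr = 3L,
                                posCut = 0.5, negCut = -0.5) {
  validateTrack(loci, "loci")
  validateTrack(geneElements, "geneElements")
  mat <- expressedMatrix(se)
  miss <- setdiff(c(loci$id, geneElements$id), rownames(mat))
  if (length(miss))
    .crsStop(paste("features missing from the expression matrix:",
                   paste(head(miss, 3), collapse = ", ")),
             "crsValidationError")
  nExp <- ncol(mat)
  rows <- list()
  for (i in seq_along(loci)) {
    crsVec <- mat[loci$id[i], ]
    eC <- sum(crsVec)
    if (eC < minExpr) next
    cf <- closestFeatures(loci[i], geneElements)
    if (nrow(cf) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        crs_id = loci$id[i], element_id = NA, gene_id = NA, distance = NA,
        side = NA, tie = FALSE, e_cg = NA, e_c = eC, e_gnc = NA,
        e_nc = nExp - eC, score = NA_real_, class = "no_neighbor")
      next
    }
    for (k in seq_len(nrow(cf))) {
      el <- geneElements[cf$featureIdx[k]]
      gVec <- mat[el$id, ]
      eCg <- sum(crsVec & gVec)
      eGnc <- sum(gVec & !crsVec)
      eNc <- nExp - eC
      score <- coexpressionScore(eCg, eC, eGnc, eNc)
      rows[[length(rows) + 1L]] <- data.frame(
        crs_id = loci$id[i], element_id = el$id, gene_id = el$gene_id,
        distance = cf$distance[k], side = cf$side[k], tie = nrow(cf) > 1L,
        e_cg = eCg, e_c = eC, e_gnc = eGnc, e_nc = eNc, score = score,
        class = if (score >= posCut) "positive" else
          if (score <= negCut) "negative" else "independent")
    }
  }
  if (!length(rows))
    return(data.frame(crs_id = character(0), element_id = character(0),
                      gene_id = character(0), distance = numeric(0),
                      side = character(0), tie = logical(0),
                      e_cg = numeric(0), e_c = numeric(0),
                      e_gnc = numeric(0), e_nc = numeric(0),
                      score = numeric(0), class = character(0)))
  do.call(rbind, rows)
}
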