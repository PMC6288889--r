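#' Merge selected motifs into strand-independent CRS loci
#'
#' Overlapping predictions on opposite strands are merged (the reading
#' direction of a conserved structure cannot be distinguished) and adjacent
#' elements separated by at most \code{maxGap} nucleotides are chained, so
#' each genomic locus is assumed to produce one product.  Locus ids are
#' assigned in (chromosome, start) order as \code{prefix} plus a 7-digit
#' counter.  The result is independent of motif input order.
#'
#' @param motifs selected motif GRanges (columns id, pscore; fdr optional)
#' @param maxGap merge gap in nt (default 30, inclusive)
#' @param prefix locus id prefix (default "DC")
#' @return unstranded GRanges of loci with mcols id, n_members, member_ids
#'   (CharacterList), best_pscore, min_fdr
#' @export
buildLoci <- function(motifs, maxGap = 30L, prefix = "DC") {
  validateTrack(motifs, "motifs")
  motifs <- BiocGenerics::sort(motifs, ignore.strand = TRUE)
  loci <- GenomicRanges::reduce(motifs, min.gapwidth = maxGap + 1L,
                                ignore.strand = TRUE, with.revmap = TRUE)
  loci <- BiocGenerics::sort(loci)
  rev <- loci$revmap
  loci$id <- sprintf("%s%07d", prefix, seq_along(loci))
  loci$n_members <- lengths(rev)
  loci$member_ids <- IRanges::extractList(motifs$id, rev)
  loci$best_pscore <- vapply(rev, function(i) max(motifs$pscore[i]),
                             numeric(1))
  loci$min_fdr <- if (!is.null(motifs$fdr))
    vapply(rev, function(i) min(motifs$fdr[i]), numeric(1)) else NA_real_
  loci$revmap <- NULL
  loci
}

#' Write a locus set as BED plus a TSV sidecar
#'
#' @param loci output of [buildLoci()]
#' @param bedPath,tsvPath output paths
#' @export
writeLoci <- function(loci, bedPath, tsvPath) {
  out <- loci
  names(out) <- out$id
  writeBed(out, bedPath)
  df <- data.frame(id = loci$id,
                   members = vapply(loci$member_ids, paste, character(1),
                                    collapse = ","),
                   best_pscore = loci$best_pscore, min_fdr = loci$min_fdr)
  write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bedPath)
}
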