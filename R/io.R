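#' Read/write BED6 tracks
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()].
#' Files are BED (0-based half-open, strand "." for unstranded); in memory the
#' intervals are GRanges (1-based closed, strand "*").  Round trips are
#' lossless for coordinates, names, and strand.
#'
#' @param path file path
#' @return a GRanges
#' @export
readBed <- function(path) {
  if (!file.exists(path))
    .crsStop(sprintf("input file not found: %s", path), "crsMissingInput")
  rtracklayer::import(path, format = "BED")
}

#' @rdname readBed
#' @param gr a GRanges to write
#' @export
writeBed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read GFF-like gene models
#'
#' Reads a GFF3 file of gene/exon/CDS records (1-based closed coordinates,
#' converted to GRanges on read).  Exon and CDS rows must carry a Parent link
#' to a gene row; an exon without a known parent is a validation error.
#'
#' @param path GFF3 file
#' @return GRanges with mcols type, ID, Parent (character)
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path))
    .crsStop(sprintf("input file not found: %s", path), "crsMissingInput")
  gr <- rtracklayer::import(path, format = "gff3")
  gr$Parent <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
  gr$Parent[gr$Parent == ""] <- NA_character_
  geneIds <- gr$ID[gr$type == "gene"]
  child <- gr$type %in% c("exon", "CDS")
  bad <- child & (is.na(gr$Parent) | !(gr$Parent %in% geneIds))
  if (any(bad))
    .crsStop(sprintf("exon/CDS without parent gene: %s",
                     paste(head(gr$ID[bad], 3), collapse = ", ")),
             "crsValidationError")
  gr
}

## columns of the motif prediction table (external interface; BED-style
## 0-based half-open coordinates in the file)
.motifCols <- c("id", "chrom", "start", "end", "strand", "pscore", "energy",
                "gc", "identity", "n_species", "source")

#' Read/write motif prediction tables
#'
#' TSV with header: id, chrom, start, end (0-based half-open), strand,
#' pscore, energy, gc, identity, n_species, source (native|shuffled), plus
#' any extra columns (e.g. fdr) which are preserved.
#'
#' @param path TSV file
#' @return GRanges with the non-coordinate columns as mcols
#' @export
readMotifTable <- function(path) {
  if (!file.exists(path))
    .crsStop(sprintf("input file not found: %s", path), "crsMissingInput")
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.motifCols, names(df))
  if (length(miss))
    .crsStop(paste("motif table missing columns:",
                   paste(miss, collapse = ", ")), "crsValidationError")
  motifTableToGRanges(df)
}

#' @rdname readMotifTable
#' @param df data.frame in the file layout
#' @export
motifTableToGRanges <- function(df) {
  if (any(df$start >= df$end))
    .crsStop(sprintf("malformed interval in record '%s': start >= end",
                     df$id[which(df$start >= df$end)[1]]),
             "crsValidationError")
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(df$start + 1L, df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[extra])
  gr
}

#' @rdname readMotifTable
#' @param gr motif GRanges as returned by [readMotifTable()]
#' @export
writeMotifTable <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  df <- as.data.frame(S4Vectors::mcols(gr))
  out <- cbind(
    df["id"],
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = sub("\\*", ".",
                            as.character(GenomicRanges::strand(gr)))),
    df[setdiff(names(df), "id")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write alignment-block metadata tables
#'
#' TSV with header: chrom, start, end (0-based half-open), n_species, gc,
#' identity.
#'
#' @param path TSV file
#' @return GRanges with mcols n_species, gc, identity
#' @export
readBlockTable <- function(path) {
  if (!file.exists(path))
    .crsStop(sprintf("input file not found: %s", path), "crsMissingInput")
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$n_species <- df$n_species
  gr$gc <- df$gc
  gr$identity <- df$identity
  gr
}

#' @rdname readBlockTable
#' @param gr block GRanges
#' @export
writeBlockTable <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    n_species = gr$n_species, gc = gr$gc,
                    identity = gr$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
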