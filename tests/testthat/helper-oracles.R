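## quick GRanges builder (1-based closed coordinates)
gr <- function(chrom, start, end, strand = "*", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}

## per-base brute-force oracle: covered fraction of each query interval,
## plain integer vectors only (independent of the interval stack)
bruteCoverageFraction <- function(query, targets) {
  qc <- as.character(GenomeInfoDb::seqnames(query))
  tc <- as.character(GenomeInfoDb::seqnames(targets))
  vapply(seq_along(query), function(i) {
    pos <- GenomicRanges::start(query)[i]:GenomicRanges::end(query)[i]
    covered <- rep(FALSE, length(pos))
    for (j in which(tc == qc[i])) {
      covered <- covered | (pos >= GenomicRanges::start(targets)[j] &
                              pos <= GenomicRanges::end(targets)[j])
    }
    sum(covered) / length(pos)
  }, numeric(1))
}

## per-base brute-force merge oracle: mark all covered positions, bridge
## gaps <= maxGap, read off runs; returns data.frame(chrom, start, end)
bruteMerge <- function(track, maxGap = 0L) {
  ch <- as.character(GenomeInfoDb::seqnames(track))
  out <- list()
  for (cc in unique(ch)) {
    idx <- which(ch == cc)
    hi <- max(GenomicRanges::end(track)[idx]) + 2L
    covered <- rep(FALSE, hi)
    for (j in idx)
      covered[GenomicRanges::start(track)[j]:GenomicRanges::end(track)[j]] <-
        TRUE
    ## bridge internal gaps of length <= maxGap
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1L && k < length(r$values) &&
          r$lengths[k] <= maxGap)
        covered[starts[k]:ends[k]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (length(on))
      out[[cc]] <- data.frame(chrom = cc, start = starts[on],
                              end = ends[on])
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

## exhaustive hypergeometric oracle for the one-sided (enrichment) Fisher
## exact test on a 2x2 table; uses choose() only
fisherOracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  tot <- m + n
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(tot, k)
  xs <- max(0, k - n):min(k, m)
  sum(vapply(xs[xs >= a], prob, numeric(1)))
}

## random motif set builder with the metadata columns the filters expect
randomMotifs <- function(n, chrom = "chrT", maxPos = 100000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- sample.int(maxPos - 200L, n, replace = TRUE)
  len <- sample(30:150, n, replace = TRUE)
  gr(chrom, st, st + len - 1L,
     strand = sample(c("+", "-"), n, replace = TRUE),
     id = sprintf("M%05d", seq_len(n)),
     pscore = runif(n, 40, 160), energy = rnorm(n, -10, 4),
     gc = runif(n), identity = runif(n),
     n_species = sample(3:27, n, replace = TRUE), source = "native")
}

## small deterministic gene-model fixture: two genes (one +, one -) and one
## non-coding gene on a 10 kb chromosome
tinyGeneModels <- function() {
  sl <- c(chrT = 10000L)
  mk <- function(start, end, strand, type, id, parent, coding) {
    GenomicRanges::GRanges("chrT", IRanges::IRanges(start, end),
                           strand = strand, type = type, ID = id,
                           Parent = parent, coding = coding,
                           seqlengths = sl)
  }
  c(
    ## gene A (+): exon1 1001-1400 (UTR5 1001-1100), intron, exon2
    ## 2001-2600 (CDS to 2400, UTR3 2401-2600)
    mk(1001, 2600, "+", "gene", "GA", NA, TRUE),
    mk(1001, 1400, "+", "exon", "GA.E1", "GA", TRUE),
    mk(2001, 2600, "+", "exon", "GA.E2", "GA", TRUE),
    mk(1101, 1400, "+", "CDS", "GA.C1", "GA", TRUE),
    mk(2001, 2400, "+", "CDS", "GA.C2", "GA", TRUE),
    ## gene B (-): single exon 5001-6000, CDS 5201-5800 so UTR3 on the
    ## left (5001-5200) and UTR5 on the right (5801-6000)
    mk(5001, 6000, "-", "gene", "GB", NA, TRUE),
    mk(5001, 6000, "-", "exon", "GB.E1", "GB", TRUE),
    mk(5201, 5800, "-", "CDS", "GB.C1", "GB", TRUE),
    ## non-coding gene C: exon 8001-8300
    mk(8001, 8300, "+", "gene", "GC", NA, FALSE),
    mk(8001, 8300, "+", "exon", "GC.E1", "GC", FALSE))
}

## compact simulation shared by end-to-end checks (generator defaults for
## distributions and rates are untouched; only the genome is smaller)
smallSimConfig <- function(seed) {
  simulationConfig(seed = seed,
                   genome = list(n_chroms = 1L, chrom_length = 150000L,
                                 n_genes = 30L, n_ncrna = 20L))
}
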