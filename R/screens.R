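#' Pairwise overlap matrix between prediction screens
#'
#' Cell (A, B) holds the number of predictions of screen A that overlap at
#' least one prediction of screen B by at least \code{minBp} nucleotides
#' (asymmetric: screens differ in prediction counts and sizes).  The diagonal
#' holds the screen sizes.
#'
#' @param screens named list of >= 2 GRanges
#' @param minBp minimum overlap in nt (default 1)
#' @return integer matrix with screen names on both dimensions
#' @export
compareScreens <- function(screens, minBp = 1L) {
  stopifnot(is.list(screens), length(screens) >= 2L,
            !is.null(names(screens)))
  n <- length(screens)
  m <- matrix(0L, n, n, dimnames = list(names(screens), names(screens)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      m[a, b] <- if (a == b) length(screens[[a]]) else
        sum(IRanges::overlapsAny(screens[[a]], screens[[b]],
                                 minoverlap = minBp, ignore.strand = TRUE))
    }
  }
  m
}

#' Expected overlap of two independent screens
#'
#' Under independence, and with predictions covering little of the genome,
#' the expected fraction of shared loci is the product of the two screens'
#' sensitivities.
#'
#' @param sensA,sensB sensitivities in [0, 1]
#' @export
expectedOverlap <- function(sensA, sensB) {
  stopifnot(all(sensA >= 0 & sensA <= 1), all(sensB >= 0 & sensB <= 1))
  sensA * sensB
}
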