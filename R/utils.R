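#' @importFrom methods new validObject is slot setClass setGeneric setMethod
#'   setValidity show
#' @importFrom stats pnorm quantile rbeta rbinom rexp rgamma rnorm rpois runif
#'   fisher.test t.test wilcox.test binom.test setNames
#' @importFrom utils read.delim write.table head
NULL

## internal: stop with a classed condition so callers can test on class
.crsStop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## clamp a numeric vector into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## round-half-up at given digits (report-time rounding of fractional counts;
## R's round() is banker's rounding which disagrees with printed tables)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## derive a stream of sub-seeds from one master seed (kept below 2^31)
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
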