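#' Create a histogram configuration
#'
#' @param bins bins per axis for \code{rule = "fixed"}; ignored (and kept
#'   \code{NA}) for \code{rule = "rice"}.
#' @param rule \code{"rice"} (default) to pick the bin count from the sample
#'   size as \eqn{\lceil 2 n^{1/3} \rceil}, or \code{"fixed"}.
#' @return a [HistogramConfig-class] object.
#' @examples
#' histogramConfig()              # Rice rule
#' histogramConfig(16, "fixed")   # always 16 bins per axis
#' @export
histogramConfig <- function(bins = NA, rule = c("rice", "fixed")) {
  rule <- match.arg(rule)
  if (rule == "rice" && !is.na(bins)) rule <- "fixed"
  new("HistogramConfig", bins = as.integer(bins), rule = rule)
}

#' Number of bins per axis for a sample of size n
#'
#' @param cfg a [HistogramConfig-class].
#' @param n sample size.
#' @return integer bin count (B >= 2).
#' @export
nBins <- function(cfg, n) {
  if (cfg@rule == "rice") max(2L, as.integer(ceiling(2 * n^(1 / 3))))
  else cfg@bins
}

## Equal-width bin assignment over [min(v), max(v)]: values exactly on an
## internal edge go to the higher bin; the top bin is right-closed.
## A constant vector maps everything to bin 1.
.binIndex <- function(v, B, lo = min(v), hi = max(v)) {
  if (hi == lo) return(rep.int(1L, length(v)))
  idx <- floor((v - lo) / (hi - lo) * B) + 1
  as.integer(pmin(pmax(idx, 1), B))
}

.entropyBits <- function(counts) {
  tot <- sum(counts)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Joint histogram of two equal-length vectors
#'
#' Equal-width B x B binning, each axis spanning that variable's observed
#' min-max range. The maximum value is assigned to the top bin; values that
#' fall exactly on an internal edge go to the higher bin.
#'
#' @param x,y numeric vectors of equal length.
#' @param cfg a [HistogramConfig-class]; default Rice rule.
#' @return integer B x B count matrix (rows index x bins) summing to
#'   \code{length(x)}.
#' @examples
#' jointHistogram(c(0, 0, 1, 1), c(0, 1, 0, 1), histogramConfig(2, "fixed"))
#' @export
jointHistogram <- function(x, y, cfg = histogramConfig()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one observation")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  B <- nBins(cfg, length(x))
  ix <- .binIndex(x, B)
  iy <- .binIndex(y, B)
  matrix(tabulate((iy - 1L) * B + ix, nbins = B * B), nrow = B, ncol = B)
}

#' Plug-in (maximum-likelihood) entropy of a count table, in bits
#'
#' \eqn{-\sum_i p_i \log_2 p_i} over non-empty cells, with
#' \eqn{p_i = c_i / \sum c}; \eqn{0 \log 0} is taken as 0.
#'
#' @param counts non-negative numeric vector or matrix of counts.
#' @return entropy in bits.
#' @examples
#' entropyFromCounts(c(1, 1, 1, 1))  # 2 bits
#' entropyFromCounts(c(2, 1, 1))     # 1.5 bits
#' @export
entropyFromCounts <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("counts must sum to at least 1")
  .entropyBits(as.vector(counts))
}
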