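#' Simulate the three canonical dependence cases
#'
#' Draws \code{x ~ Uniform[0, 1]} and builds three responses with known
#' dependence structure, each with its own additive zero-mean Gaussian
#' noise draw:
#' \itemize{
#'   \item Case I (purely linear): \eqn{y_1 = 2x + \epsilon}
#'   \item Case II (purely quadratic, zero linear correlation):
#'     \eqn{y_2 = 5(x - 0.5)^2 + \epsilon}
#'   \item Case III (mixed): \eqn{y_3 = 5(x - 0.5)^2 + 2x + \epsilon}
#' }
#' With \code{noiseSd = 0.1} the population correlation of Case I is
#' \eqn{\sqrt{(1/3)/(1/3 + \sigma^2)} \approx 0.985} and of Case III
#' \eqn{\approx 0.831}; Case II has population correlation 0 because
#' \eqn{(x - 0.5)^2} is symmetric about the mean of \eqn{x}.
#'
#' @param n sample count (default 1000).
#' @param noiseSd standard deviation of the Gaussian noise (default 0.1).
#' @param seed optional integer seed for reproducibility.
#' @return list with numeric vectors \code{x}, \code{y1}, \code{y2},
#'   \code{y3}.
#' @examples
#' s <- simulateThreeCases(seed = 1)
#' cor(s$x, s$y1)  # close to 0.985
#' @export
simulateThreeCases <- function(n = 1000, noiseSd = 0.1, seed = NULL) {
  if (n < 10) stop("n must be at least 10")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n)
  list(x = x,
       y1 = 2 * x + stats::rnorm(n, 0, noiseSd),
       y2 = 5 * (x - 0.5)^2 + stats::rnorm(n, 0, noiseSd),
       y3 = 5 * (x - 0.5)^2 + 2 * x + stats::rnorm(n, 0, noiseSd))
}

#' Dependence summary of the three simulated cases
#'
#' For each case, the Pearson correlation and NMI of the pair before
#' residualization, and again after removing the OLS-fitted linear
#' component of y on x. The post-removal correlation is zero up to
#' floating-point error by construction; the post-removal NMI isolates the
#' nonlinear dependence.
#'
#' @param cases list as returned by [simulateThreeCases()].
#' @param cfg a [HistogramConfig-class].
#' @param normalization NMI normalizer, see
#'   [normalizedMutualInformation()].
#' @return data.frame with one row per case and columns \code{case},
#'   \code{corr_before}, \code{corr_after}, \code{nmi_before},
#'   \code{nmi_after}.
#' @export
caseSummary <- function(cases, cfg = histogramConfig(),
                        normalization = c("max", "joint")) {
  normalization <- match.arg(normalization)
  x <- cases$x
  one <- function(y) {
    z <- removeLinear(x, y)$residual
    c(corr_before = pearsonCorrelation(x, y),
      corr_after = stats::cor(x, z),
      nmi_before = normalizedMutualInformation(x, y, cfg, normalization)$nmi,
      nmi_after = normalizedMutualInformation(x, z, cfg, normalization)$nmi)
  }
  out <- rbind(one(cases$y1), one(cases$y2), one(cases$y3))
  data.frame(case = c("I", "II", "III"), out, row.names = NULL)
}
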