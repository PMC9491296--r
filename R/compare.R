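#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Adjusted value for the i-th ranked p value is
#' \eqn{\min_{j \ge i} m \, p_{(j)} / j}, capped at 1 (the standard
#' step-up procedure as in \code{p.adjust(method = "BH")}); the mask
#' rejects where the adjusted value is at or below \code{alpha}.
#'
#' @param p numeric vector of p values in [0, 1] (NA allowed; propagated).
#' @param alpha FDR level (default 0.05).
#' @return list with \code{adjusted} (numeric) and \code{mask} (logical;
#'   \code{FALSE} where p is NA).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  adjusted <- stats::p.adjust(p, method = "BH")
  mask <- !is.na(adjusted) & adjusted <= alpha
  list(adjusted = adjusted, mask = mask)
}

## helpers shared by the two comparison procedures -------------------------

## pairs in the same (column-major) order that m[upper.tri(m)] extracts
.upperPairs <- function(C) {
  which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
}

.stackCells <- function(matrices) {
  ## subjects x cells matrix of upper-triangle values
  C <- nrow(connValues(matrices[[1L]]))
  ut <- upper.tri(matrix(0, C, C))
  t(vapply(matrices, function(m) connValues(m)[ut], numeric(sum(ut))))
}

.symmetrize <- function(vec, C, labels, diagval = NA) {
  m <- matrix(diagval, C, C, dimnames = list(labels, labels))
  ut <- upper.tri(m)
  m[ut] <- vec
  m <- t(m)
  m[ut] <- vec
  m
}

.comparisonFromCells <- function(tv, pv, metric, C, labels, alpha, test) {
  adj <- bhFdr(pv, alpha)
  slp <- -log10(pv) * sign(tv)
  new("FncGroupComparison", metric = metric,
      tMap = .symmetrize(tv, C, labels),
      pMap = .symmetrize(pv, C, labels),
      qMap = .symmetrize(adj$adjusted, C, labels),
      signedLogP = .symmetrize(slp, C, labels),
      mask = .symmetrize(adj$mask, C, labels, diagval = FALSE),
      alpha = alpha, test = test)
}

#' Test every cell against the minimum-mean cell
#'
#' Identifies the off-diagonal cell with the lowest mean across subjects
#' and, for every other off-diagonal cell, tests whether its subject-wise
#' values are greater than the minimum cell's (one-sided). The default is
#' a paired t-test of the per-subject differences; \code{paired = FALSE}
#' instead tests each cell's values against the scalar minimum mean
#' (one-sample reading). p values are BH-adjusted over the tested cells.
#' The minimum cell itself, and any cell whose differences have zero
#' variance, is reported untested (NA, unmasked).
#'
#' @param matrices list of [FncMatrix-class] (>= 3 subjects), same metric.
#' @param alpha FDR level.
#' @param paired logical; paired differences (default) or scalar-mean
#'   reading.
#' @return an [FncGroupComparison-class]; the minimum-mean cell indices are
#'   attached as attribute \code{"minCell"}.
#' @export
minCellTest <- function(matrices, alpha = 0.05, paired = TRUE) {
  if (length(matrices) < 3L) stop("need at least 3 subjects")
  metrics <- unique(vapply(matrices, metricName, character(1)))
  if (length(metrics) != 1L) stop("mixed metrics")
  C <- nrow(connValues(matrices[[1L]]))
  labels <- rownames(connValues(matrices[[1L]]))
  cells <- .stackCells(matrices)              # subjects x nCells
  means <- colMeans(cells)
  minIdx <- which.min(means)
  ref <- cells[, minIdx]
  nCells <- ncol(cells)
  tv <- pv <- rep(NA_real_, nCells)
  for (k in seq_len(nCells)) {
    if (k == minIdx) next
    d <- if (paired) cells[, k] - ref else cells[, k] - means[minIdx]
    if (stats::sd(d) == 0) next
    tt <- stats::t.test(d, alternative = "greater")
    tv[k] <- unname(tt$statistic)
    pv[k] <- tt$p.value
  }
  out <- .comparisonFromCells(tv, pv, metrics, C, labels, alpha,
                              test = if (paired) "min-cell paired t"
                                     else "min-cell one-sample t")
  pairs <- .upperPairs(C)
  attr(out, "minCell") <- pairs[minIdx, ]
  out
}

#' Two-sample group comparison of connectivity matrices
#'
#' Per off-diagonal cell, a two-sample t-test of group A versus group B
#' (A - B orientation; Student's pooled-variance by default, Welch with
#' \code{welch = TRUE}), BH-adjusted across the C(C-1)/2 unique cells.
#' The signed log-p map is \eqn{-\log_{10}(p_{raw}) \cdot sign(t)}.
#' Optionally Fisher z-transforms pearson/boosted values before testing.
#'
#' @param groupA,groupB lists of [FncMatrix-class] (>= 2 subjects each),
#'   same metric and dimension.
#' @param alpha FDR level.
#' @param welch use Welch's unequal-variance t-test.
#' @param fisherZ apply \code{atanh} to the cell values before testing
#'   (only meaningful for correlation-like metrics).
#' @return an [FncGroupComparison-class].
#' @export
twoSampleCompare <- function(groupA, groupB, alpha = 0.05, welch = FALSE,
                             fisherZ = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 subjects per group")
  mA <- unique(vapply(groupA, metricName, character(1)))
  mB <- unique(vapply(groupB, metricName, character(1)))
  if (length(mA) != 1L || !identical(mA, mB))
    stop("metric mismatch between groups")
  C <- nrow(connValues(groupA[[1L]]))
  if (nrow(connValues(groupB[[1L]])) != C) stop("dimension mismatch")
  labels <- rownames(connValues(groupA[[1L]]))
  a <- .stackCells(groupA)
  b <- .stackCells(groupB)
  if (fisherZ) { a <- atanh(pmin(pmax(a, -1 + 1e-15), 1 - 1e-15))
                 b <- atanh(pmin(pmax(b, -1 + 1e-15), 1 - 1e-15)) }
  nCells <- ncol(a)
  tv <- pv <- rep(NA_real_, nCells)
  for (k in seq_len(nCells)) {
    if (stats::sd(a[, k]) == 0 && stats::sd(b[, k]) == 0) {
      if (mean(a[, k]) == mean(b[, k])) { tv[k] <- 0; pv[k] <- 1 }
      next
    }
    tt <- stats::t.test(a[, k], b[, k], var.equal = !welch)
    tv[k] <- unname(tt$statistic)
    pv[k] <- tt$p.value
  }
  .comparisonFromCells(tv, pv, mA, C, labels, alpha,
                       test = if (welch) "two-sample Welch t"
                              else "two-sample pooled t")
}

#' Most significant component pairs of a comparison
#'
#' The k off-diagonal pairs with the smallest raw p values; ties are broken
#' by larger |t|, then by (i, j) lexicographic order.
#'
#' @param comparison an [FncGroupComparison-class].
#' @param k number of pairs (default 5).
#' @return data.frame with columns \code{i}, \code{j}, \code{label_i},
#'   \code{label_j}, \code{t}, \code{p}, \code{q}.
#' @export
selectTopPairs <- function(comparison, k = 5) {
  C <- nrow(comparison@pMap)
  pairs <- .upperPairs(C)
  if (k < 1 || k > nrow(pairs)) stop("k out of range")
  p <- comparison@pMap[pairs]
  t_ <- comparison@tMap[pairs]
  ord <- order(p, -abs(t_), pairs[, 1L], pairs[, 2L], na.last = TRUE)
  sel <- ord[seq_len(k)]
  labels <- rownames(comparison@pMap)
  data.frame(i = pairs[sel, 1L], j = pairs[sel, 2L],
             label_i = labels[pairs[sel, 1L]],
             label_j = labels[pairs[sel, 2L]],
             t = t_[sel], p = p[sel], q = comparison@qMap[pairs][sel],
             row.names = NULL)
}

#' Significant-edge table of a group comparison
#'
#' Tabular equivalent of a connectogram: one row per significant cell with
#' component indices, labels, optional domains, t, p, q and the sign of
#' the difference.
#'
#' @param comparison an [FncGroupComparison-class].
#' @param domains optional character vector of per-component domains.
#' @return data.frame, empty when nothing is significant.
#' @export
significantEdges <- function(comparison, domains = NULL) {
  C <- nrow(comparison@mask)
  pairs <- .upperPairs(C)
  keep <- comparison@mask[pairs]
  keep[is.na(keep)] <- FALSE
  pairs <- pairs[keep, , drop = FALSE]
  labels <- rownames(comparison@mask)
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                    label_i = labels[pairs[, 1L]],
                    label_j = labels[pairs[, 2L]],
                    t = comparison@tMap[pairs],
                    p = comparison@pMap[pairs],
                    q = comparison@qMap[pairs],
                    sign = sign(comparison@tMap[pairs]), row.names = NULL)
  if (!is.null(domains)) {
    out$domain_i <- domains[out$i]
    out$domain_j <- domains[out$j]
  }
  out
}
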