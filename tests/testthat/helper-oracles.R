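## Independent brute-force oracles. These re-derive the quantities from
## their definitions with naive loops so the tests never share code with
## the implementation paths they check.

## per-sample loop bin assignment over [min, max] equal-width bins,
## top bin right-closed, internal-edge values to the higher bin
oracle_hist2d <- function(x, y, B) {
  assign1 <- function(v, lo, hi) {
    if (hi == lo) return(rep(1L, length(v)))
    w <- (hi - lo) / B
    out <- integer(length(v))
    for (t in seq_along(v)) {
      k <- 1L
      while (k < B && v[t] >= lo + k * w) k <- k + 1L
      out[t] <- k
    }
    out
  }
  ix <- assign1(x, min(x), max(x))
  iy <- assign1(y, min(y), max(y))
  counts <- matrix(0L, B, B)
  for (t in seq_along(x))
    counts[ix[t], iy[t]] <- counts[ix[t], iy[t]] + 1L
  counts
}

oracle_entropy <- function(counts) {
  p <- as.vector(counts) / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

## MI directly from the joint table: sum_ij p_ij log2(p_ij / (p_i p_j))
oracle_mi <- function(joint) {
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  mi
}

## literal BH step-up: adjusted_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[ord[j]] / j)
    adj[ord[i]] <- min(1, best)
  }
  adj
}

## hand-rolled FncCohort from a list of matrices (equal split A/B unless
## groups given)
make_cohort <- function(mats, groups = NULL, domains = character()) {
  n <- length(mats)
  if (is.null(groups)) groups <- rep(c("A", "B"), each = ceiling(n / 2))[1:n]
  new("FncCohort", timecourses = mats,
      subjectId = sprintf("S%03d", seq_len(n)), group = groups,
      componentLabels = sprintf("C%02d", seq_len(ncol(mats[[1]]))),
      domains = domains)
}

## FncMatrix from a plain symmetric matrix
make_fnc <- function(v, metric = "pearson") {
  if (is.null(dimnames(v)))
    dimnames(v) <- list(sprintf("C%02d", seq_len(nrow(v))),
                        sprintf("C%02d", seq_len(nrow(v))))
  new("FncMatrix", metric = metric, values = v)
}
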