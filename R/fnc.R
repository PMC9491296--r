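## Fast internal paths used by the matrix builders: plain vectors in, plain
## numbers out, no S4 dispatch or argument matching inside the pair loop.

.nmiFast <- function(x, y, B, normMax = TRUE) {
  ix <- .binIndex(x, B)
  iy <- .binIndex(y, B)
  joint <- matrix(tabulate((iy - 1L) * B + ix, nbins = B * B), B, B)
  hx <- .entropyBits(rowSums(joint))
  hy <- .entropyBits(colSums(joint))
  hxy <- .entropyBits(as.vector(joint))
  norm <- if (normMax) max(hx, hy) else hxy
  if (norm == 0) 0 else (hx + hy - hxy) / norm
}

.residFast <- function(x, y) {
  a <- stats::cov(x, y) / stats::var(x)
  y - (a * x + (mean(y) - a * mean(x)))
}

.enmiFast <- function(x, y, B, normMax = TRUE) {
  zy <- .residFast(x, y)
  zx <- .residFast(y, x)
  a <- if (stats::sd(zy) <= 1e-10 * stats::sd(y)) 0
       else .nmiFast(x, zy, B, normMax)
  b <- if (stats::sd(zx) <= 1e-10 * stats::sd(x)) 0
       else .nmiFast(y, zx, B, normMax)
  0.5 * (a + b)
}

#' Connectivity matrix for one subject
#'
#' Fills all unordered component pairs of a T x C time-course matrix with
#' the chosen dependence metric. The diagonal is 1 for \code{"pearson"}
#' and \code{"boosted"}, 0 for \code{"enmi"} (a component's self-residual
#' is the zero vector). A constant component cannot carry dependence: its
#' row and column are set to the metric's degenerate value (0, or \code{NA}
#' for pearson) with a warning.
#'
#' @param timecourses numeric T x C matrix (rows = timepoints) or an
#'   [FncCohort-class] together with \code{subject}.
#' @param metric \code{"pearson"}, \code{"enmi"} or \code{"boosted"}.
#' @param cfg a [HistogramConfig-class].
#' @param normalization NMI normalizer, see
#'   [normalizedMutualInformation()].
#' @param subject subject id or index when \code{timecourses} is a cohort.
#' @return an [FncMatrix-class].
#' @export
subjectFnc <- function(timecourses, metric = c("pearson", "enmi", "boosted"),
                       cfg = histogramConfig(),
                       normalization = c("max", "joint"), subject = NULL) {
  metric <- match.arg(metric)
  normalization <- match.arg(normalization)
  if (is(timecourses, "FncCohort")) {
    labels <- componentLabels(timecourses)
    timecourses <- timeCourses(timecourses, subject)
  } else {
    labels <- colnames(timecourses)
    if (is.null(labels)) labels <- sprintf("C%02d", seq_len(ncol(timecourses)))
  }
  T_ <- nrow(timecourses)
  C <- ncol(timecourses)
  if (T_ < 10) stop("need at least 10 timepoints")
  normMax <- normalization == "max"
  B <- nBins(cfg, T_)
  sds <- apply(timecourses, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat))
    warning("constant component(s) ", paste(labels[flat], collapse = ", "),
            ": row/column set to the degenerate value")
  ok <- setdiff(seq_len(C), flat)

  v <- matrix(if (metric == "pearson") NA_real_ else 0, C, C,
              dimnames = list(labels, labels))
  if (metric == "pearson") {
    v[ok, ok] <- stats::cor(timecourses[, ok, drop = FALSE])
    diag(v) <- 1
  } else {
    for (a in seq_along(ok)) for (b in seq_len(a - 1L)) {
      i <- ok[b]; j <- ok[a]
      e <- .enmiFast(timecourses[, i], timecourses[, j], B, normMax)
      if (metric == "boosted") {
        rho <- stats::cor(timecourses[, i], timecourses[, j])
        e <- rho + sign(rho) * e
      }
      v[i, j] <- v[j, i] <- e
    }
    diag(v) <- if (metric == "boosted") 1 else 0
  }
  if (metric == "pearson" && length(flat)) {
    v[flat, ] <- NA_real_; v[, flat] <- NA_real_; diag(v) <- 1
  }
  new("FncMatrix", metric = metric, values = v)
}

#' Connectivity matrices for every subject of a cohort
#'
#' @param cohort an [FncCohort-class].
#' @inheritParams subjectFnc
#' @return named list of [FncMatrix-class], one per subject.
#' @export
cohortFnc <- function(cohort, metric = c("pearson", "enmi", "boosted"),
                      cfg = histogramConfig(),
                      normalization = c("max", "joint")) {
  metric <- match.arg(metric)
  normalization <- match.arg(normalization)
  out <- lapply(seq_len(nSubjects(cohort)), function(s)
    subjectFnc(timeCourses(cohort, s), metric, cfg, normalization))
  names(out) <- subjectIds(cohort)
  out
}

#' Element-wise mean of connectivity matrices
#'
#' @param matrices non-empty list of [FncMatrix-class] sharing metric and
#'   dimension.
#' @return an [FncMatrix-class] of the same metric.
#' @export
groupMeanFnc <- function(matrices) {
  if (length(matrices) == 0L) stop("no matrices supplied")
  metrics <- vapply(matrices, metricName, character(1))
  if (length(unique(metrics)) != 1L)
    stop("cannot average matrices of mixed metrics")
  dims <- vapply(matrices, function(m) nrow(connValues(m)), integer(1))
  if (length(unique(dims)) != 1L)
    stop("cannot average matrices of mixed dimensions")
  mean_v <- Reduce(`+`, lapply(matrices, connValues)) / length(matrices)
  new("FncMatrix", metric = metrics[1L], values = mean_v)
}
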