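#' @import methods
NULL

#' Histogram estimator configuration
#'
#' Controls the equal-width histogram used by the plug-in entropy estimator.
#' With \code{rule = "rice"} the number of bins per axis is chosen from the
#' sample size as \eqn{B = \lceil 2 n^{1/3} \rceil} (B = 20 at n = 1000,
#' B = 11 at n = 159); with \code{rule = "fixed"} the \code{bins} slot is
#' used as-is.
#'
#' @slot bins integer; bins per axis when \code{rule = "fixed"}, otherwise
#'   \code{NA}.
#' @slot rule character; \code{"rice"} or \code{"fixed"}.
#'
#' @seealso [histogramConfig()], [jointHistogram()],
#'   [normalizedMutualInformation()]
#' @exportClass HistogramConfig
setClass("HistogramConfig",
  representation(bins = "integer", rule = "character"),
  prototype(bins = NA_integer_, rule = "rice"))

setValidity("HistogramConfig", function(object) {
  if (length(object@rule) != 1L || !object@rule %in% c("rice", "fixed"))
    return("'rule' must be \"rice\" or \"fixed\"")
  if (object@rule == "fixed" &&
      (length(object@bins) != 1L || is.na(object@bins) || object@bins < 2L))
    return("fixed rule requires an integer 'bins' >= 2")
  TRUE
})

#' Multi-subject cohort of component time courses
#'
#' Container for a cohort of subjects, each carrying a T x C matrix of
#' component time courses (rows = timepoints, columns = components), plus
#' subject metadata (id, group) and optional component domain labels.
#'
#' @slot timecourses list of numeric T x C matrices, one per subject.
#' @slot subjectId character vector of unique subject identifiers.
#' @slot group character vector of group labels, parallel to
#'   \code{subjectId}.
#' @slot componentLabels character vector of length C.
#' @slot domains character vector of length C assigning each component to a
#'   functional domain, or length 0 when no assignment is available.
#'
#' @seealso [simulateCohort()], [readCohort()], [cohortFnc()]
#' @exportClass FncCohort
setClass("FncCohort",
  representation(timecourses = "list", subjectId = "character",
                 group = "character", componentLabels = "character",
                 domains = "character"))

setValidity("FncCohort", function(object) {
  n <- length(object@timecourses)
  if (n == 0L) return("cohort must contain at least one subject")
  if (length(object@subjectId) != n || length(object@group) != n)
    return("subjectId and group must have one entry per subject")
  if (anyDuplicated(object@subjectId))
    return("subject ids must be unique")
  dims <- vapply(object@timecourses, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all subjects must share the same T x C dimensions")
  if (!all(vapply(object@timecourses,
                  function(m) is.numeric(m) && all(is.finite(m)), logical(1))))
    return("time courses must be finite numeric matrices")
  C <- dims[2, 1]
  if (length(object@componentLabels) != C)
    return("componentLabels must have one entry per component")
  if (length(object@domains) != 0L && length(object@domains) != C)
    return("domains must be empty or have one entry per component")
  TRUE
})

#' Per-subject functional network connectivity matrix
#'
#' A symmetric C x C matrix of pairwise dependence values for one subject
#' under one metric. The diagonal is 1 for \code{"pearson"} and
#' \code{"boosted"} (self-correlation) and 0 for \code{"enmi"} (the
#' self-residual is the zero vector).
#'
#' @slot metric character; one of \code{"pearson"}, \code{"enmi"},
#'   \code{"boosted"}.
#' @slot values numeric symmetric matrix with component labels as dimnames.
#'
#' @seealso [subjectFnc()], [groupMeanFnc()]
#' @exportClass FncMatrix
setClass("FncMatrix",
  representation(metric = "character", values = "matrix"))

setValidity("FncMatrix", function(object) {
  if (!object@metric %in% c("pearson", "enmi", "boosted"))
    return("metric must be pearson, enmi or boosted")
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (isTRUE(max(abs(v - t(v)), na.rm = TRUE) > 1e-12))
    return("values must be symmetric")
  if (object@metric == "pearson" && isTRUE(max(abs(v), na.rm = TRUE) > 1 + 1e-12))
    return("pearson values must lie in [-1, 1]")
  if (object@metric == "enmi" &&
      (isTRUE(min(v, na.rm = TRUE) < -1e-12) ||
       isTRUE(max(v, na.rm = TRUE) > 1 + 1e-12)))
    return("enmi values must lie in [0, 1]")
  TRUE
})

#' Cell-wise group comparison of connectivity matrices
#'
#' Holds per-cell t statistics, raw and BH-adjusted p values, the signed
#' -log10(p) map used for visualization, and the significance mask at the
#' configured FDR level. All maps are symmetric; the diagonal is excluded
#' from testing and carries \code{NA}.
#'
#' @slot metric character metric name the comparison was computed on.
#' @slot tMap,pMap,qMap,signedLogP numeric C x C matrices.
#' @slot mask logical C x C matrix, \code{TRUE} where the BH-adjusted p
#'   value falls at or below \code{alpha}.
#' @slot alpha numeric FDR level.
#' @slot test character description of the test performed.
#'
#' @seealso [twoSampleCompare()], [minCellTest()], [selectTopPairs()]
#' @exportClass FncGroupComparison
setClass("FncGroupComparison",
  representation(metric = "character", tMap = "matrix", pMap = "matrix",
                 qMap = "matrix", signedLogP = "matrix", mask = "matrix",
                 alpha = "numeric", test = "character"))

setValidity("FncGroupComparison", function(object) {
  for (nm in c("tMap", "pMap", "qMap", "signedLogP", "mask")) {
    m <- slot(object, nm)
    if (nrow(m) != ncol(m)) return(paste(nm, "must be square"))
    if (nrow(m) != nrow(object@tMap)) return("maps must share dimensions")
  }
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (any(diag(object@mask), na.rm = TRUE))
    return("mask must exclude the diagonal")
  TRUE
})

#' Permutation block-modularity result
#'
#' Result of the permutation test of domain-block structure in a mean
#' connectivity matrix: the observed statistic (mean within-domain cell
#' minus mean between-domain cell), the permutation null distribution
#' obtained by shuffling component domain labels, and the one-sided p
#' value \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @slot observed numeric observed statistic.
#' @slot nullDistribution numeric vector of permuted statistics.
#' @slot pValue numeric in (0, 1].
#'
#' @seealso [blockModularityTest()]
#' @exportClass ModularityResult
setClass("ModularityResult",
  representation(observed = "numeric", nullDistribution = "numeric",
                 pValue = "numeric"))

setValidity("ModularityResult", function(object) {
  if (length(object@pValue) != 1L || object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' Group difference of a pair's joint distribution
#'
#' For one component pair, the difference between the two groups' mean
#' joint density histograms, computed on bin edges shared across all
#' subjects (pooled min-max), so the difference grid sums to ~0.
#'
#' @slot pair integer vector of length 2 (component indices i, j).
#' @slot grid numeric G x G matrix, mean group-A density minus mean
#'   group-B density.
#' @slot xEdges,yEdges numeric bin edge vectors of length G + 1.
#'
#' @seealso [jointDistributionDifference()]
#' @exportClass JointDistDifference
setClass("JointDistDifference",
  representation(pair = "integer", grid = "matrix", xEdges = "numeric",
                 yEdges = "numeric"))

setValidity("JointDistDifference", function(object) {
  if (length(object@pair) != 2L) return("pair must have length 2")
  if (nrow(object@grid) + 1L != length(object@xEdges) ||
      ncol(object@grid) + 1L != length(object@yEdges))
    return("edge vectors must have one more entry than the grid axis")
  if (abs(sum(object@grid)) > 1e-10)
    return("difference of two densities must sum to ~0")
  TRUE
})
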