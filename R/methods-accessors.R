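#' @rdname FncCohort-class
#' @export
setMethod("nSubjects", "FncCohort", function(x) length(x@timecourses))

#' @rdname FncCohort-class
#' @export
setMethod("nComponents", "FncCohort",
          function(x) ncol(x@timecourses[[1L]]))

#' @rdname FncCohort-class
#' @export
setMethod("nTimepoints", "FncCohort",
          function(x) nrow(x@timecourses[[1L]]))

#' @rdname FncCohort-class
#' @export
setMethod("subjectIds", "FncCohort", function(x) x@subjectId)

#' @rdname FncCohort-class
#' @export
setMethod("subjectGroups", "FncCohort",
          function(x) structure(x@group, names = x@subjectId))

#' @rdname FncCohort-class
#' @export
setMethod("componentLabels", "FncCohort", function(x) x@componentLabels)

#' @rdname FncCohort-class
#' @export
setMethod("domains", "FncCohort", function(x) x@domains)

#' @rdname FncCohort-class
#' @export
setMethod("timeCourses", "FncCohort", function(x, subject) {
  if (is.character(subject)) {
    subject <- match(subject, x@subjectId)
    if (is.na(subject)) stop("unknown subject id")
  }
  x@timecourses[[subject]]
})

setMethod("show", "FncCohort", function(object) {
  cat("FncCohort:", nSubjects(object), "subjects,",
      nComponents(object), "components,",
      nTimepoints(object), "timepoints\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(object@group)),
                                 table(object@group)), collapse = ", "), "\n")
  if (length(object@domains))
    cat("  domains:", paste(unique(object@domains), collapse = ", "), "\n")
})

#' @rdname FncMatrix-class
#' @param x,object an \code{FncMatrix}.
#' @export
setMethod("metricName", "FncMatrix", function(x) x@metric)

#' @rdname FncMatrix-class
#' @export
setMethod("connValues", "FncMatrix", function(x) x@values)

setMethod("show", "FncMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("FncMatrix (%s): %d x %d, off-diagonal range [%.4f, %.4f]\n",
              object@metric, nrow(v), ncol(v), min(off), max(off)))
})

setMethod("show", "FncGroupComparison", function(object) {
  ut <- upper.tri(object@mask)
  cat(sprintf(
    "FncGroupComparison (%s, %s): %d components, %d / %d cells significant at FDR %.3g\n",
    object@metric, object@test, nrow(object@mask),
    sum(object@mask[ut], na.rm = TRUE), sum(ut), object@alpha))
})

setMethod("show", "ModularityResult", function(object) {
  cat(sprintf(
    "ModularityResult: observed %.4f, permutation p = %.4g (n_perm = %d)\n",
    object@observed, object@pValue, length(object@nullDistribution)))
})

setMethod("show", "JointDistDifference", function(object) {
  cat(sprintf(
    "JointDistDifference: pair (%d, %d), %d x %d grid, |values| up to %.3g\n",
    object@pair[1L], object@pair[2L], nrow(object@grid), ncol(object@grid),
    max(abs(object@grid))))
})
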