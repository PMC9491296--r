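#' @rdname FncCohort-class
#' @param x,object an object.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname FncCohort-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname FncCohort-class
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname FncCohort-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FncCohort-class
#' @export
setGeneric("subjectGroups", function(x) standardGeneric("subjectGroups"))

#' @rdname FncCohort-class
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' @rdname FncCohort-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname FncCohort-class
#' @param subject a subject id (character) or index (integer).
#' @export
setGeneric("timeCourses", function(x, subject) standardGeneric("timeCourses"))

#' @rdname FncMatrix-class
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname FncMatrix-class
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
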