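#' Group difference of a component pair's joint distribution
#'
#' For each subject, the pair's two time courses are binned into a G x G
#' density histogram (counts / T) on bin edges shared across *all*
#' subjects of both groups (pooled min-max per component), so the
#' densities are directly comparable. The result is the mean group-A
#' density minus the mean group-B density; it sums to ~0 and its sign
#' structure shows where one group's joint activity mass sits relative to
#' the other's.
#'
#' @param cohort an [FncCohort-class] with exactly two groups, or a list of
#'   two lists of T x C matrices via \code{groupA}/\code{groupB}.
#' @param pair integer vector (i, j) of component indices.
#' @param gridSize bins per axis G (default 20).
#' @return a [JointDistDifference-class].
#' @export
jointDistributionDifference <- function(cohort, pair, gridSize = 20) {
  if (!is(cohort, "FncCohort")) stop("cohort must be an FncCohort")
  grp <- unique(subjectGroups(cohort))
  if (length(grp) != 2L) stop("need exactly two groups")
  if (length(pair) != 2L || any(pair < 1) || any(pair > nComponents(cohort)))
    stop("pair must index two components")
  G <- as.integer(gridSize)
  if (G < 2L) stop("gridSize must be at least 2")
  i <- pair[1L]; j <- pair[2L]
  xs <- lapply(seq_len(nSubjects(cohort)),
               function(s) timeCourses(cohort, s)[, i])
  ys <- lapply(seq_len(nSubjects(cohort)),
               function(s) timeCourses(cohort, s)[, j])
  xr <- range(unlist(xs)); yr <- range(unlist(ys))
  dens <- function(x, y) {
    ix <- .binIndex(x, G, xr[1L], xr[2L])
    iy <- .binIndex(y, G, yr[1L], yr[2L])
    matrix(tabulate((iy - 1L) * G + ix, nbins = G * G), G, G) / length(x)
  }
  groupMean <- function(g) {
    idx <- which(subjectGroups(cohort) == g)
    Reduce(`+`, lapply(idx, function(s) dens(xs[[s]], ys[[s]]))) / length(idx)
  }
  gs <- sort(grp)
  grid <- groupMean(gs[1L]) - groupMean(gs[2L])
  new("JointDistDifference", pair = as.integer(pair), grid = grid,
      xEdges = seq(xr[1L], xr[2L], length.out = G + 1L),
      yEdges = seq(yr[1L], yr[2L], length.out = G + 1L))
}
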