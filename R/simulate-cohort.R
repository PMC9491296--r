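#' Simulate a two-group cohort of component time courses
#'
#' A stylized stand-in for ICA component time courses: each component is
#' its own Gaussian noise plus contributions from shared latent factors.
#' For a linearly coupled pair both components load the same standardized
#' factor \eqn{u} with weight \eqn{\lambda}, giving population correlation
#' \eqn{\lambda^2 / (1 + \lambda^2)}. For a quadratically coupled pair the
#' first component loads \eqn{u} and the second loads the standardized,
#' centered \eqn{u^2} with weight \eqn{\gamma}; since \eqn{Cov(u, u^2) = 0}
#' for Gaussian \eqn{u}, the pair is dependent but linearly uncorrelated,
#' mirroring a purely quadratic relationship. Group "B" adds
#' \code{groupDelta} to \eqn{\gamma} on the designated pairs, creating a
#' purely nonlinear group difference. Each component is optionally passed
#' through an AR(1) recursive filter (mimicking the temporal autocorrelation
#' of band-limited fMRI time courses) and finally standardized.
#'
#' Couplings are given as data frames with columns \code{i}, \code{j},
#' \code{weight} (and, for \code{nonlinearPairs}, an optional \code{delta}
#' column overridden by \code{groupDelta}).
#'
#' @param nPerGroup subjects per group (groups are labelled "A" and "B").
#' @param nComponents number of components C.
#' @param nTimepoints timepoints T per component (default 159).
#' @param componentDomains character vector of length C assigning each
#'   component to a domain; default splits components into three domains.
#' @param linearPairs data.frame(i, j, weight) of linear couplings
#'   \eqn{\lambda}; default couples consecutive within-domain pairs at 0.5.
#' @param nonlinearPairs data.frame(i, j, weight) of quadratic couplings
#'   \eqn{\gamma}; default none.
#' @param groupDelta additive change of \eqn{\gamma} in group "B", either a
#'   single number applied to every nonlinear pair or a vector with one
#'   entry per row of \code{nonlinearPairs} (default 0: exchangeable
#'   groups).
#' @param noiseSd standard deviation of each component's own noise
#'   (default 1).
#' @param arCoefficient AR(1) coefficient in [0, 1) applied to every
#'   component (default 0.3).
#' @param seed integer seed; per-subject sub-seeds are derived from it so
#'   the cohort is reproducible subject by subject.
#' @return an [FncCohort-class].
#' @examples
#' coh <- simulateCohort(nPerGroup = 5, nComponents = 6, seed = 1)
#' nSubjects(coh)
#' @export
simulateCohort <- function(nPerGroup = 20,
                           nComponents = 10,
                           nTimepoints = 159,
                           componentDomains = NULL,
                           linearPairs = NULL,
                           nonlinearPairs = NULL,
                           groupDelta = 0,
                           noiseSd = 1,
                           arCoefficient = 0.3,
                           seed = NULL) {
  C <- as.integer(nComponents)
  T_ <- as.integer(nTimepoints)
  if (nPerGroup < 1 || C < 2 || T_ < 10) stop("cohort dimensions too small")
  if (abs(arCoefficient) >= 1) stop("arCoefficient must lie in (-1, 1)")
  if (is.null(componentDomains))
    componentDomains <- sort(rep_len(paste0("D", 1:3), C))
  if (length(componentDomains) != C)
    stop("componentDomains must have one entry per component")
  if (is.null(linearPairs)) linearPairs <- .defaultLinearPairs(componentDomains)
  if (is.null(nonlinearPairs))
    nonlinearPairs <- data.frame(i = integer(), j = integer(),
                                 weight = numeric())
  .checkPairs(linearPairs, C)
  .checkPairs(nonlinearPairs, C)
  nNl <- nrow(nonlinearPairs)
  if (!length(groupDelta) %in% c(1L, max(1L, nNl)))
    stop("groupDelta must be a scalar or match nrow(nonlinearPairs)")
  delta <- if (nNl) rep_len(groupDelta, nNl) else numeric()

  if (!is.null(seed)) set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, 2L * nPerGroup)

  groups <- rep(c("A", "B"), each = nPerGroup)
  ids <- sprintf("%s%03d", groups, c(seq_len(nPerGroup), seq_len(nPerGroup)))
  ## variance-neutral group contrast: each nonlinear coupling contributes
  ## the across-group maximum variance in both groups, topped up with
  ## independent noise, so delta changes only the pair's dependence
  ## structure and never the marginal variance shares of its components
  gammaA <- nonlinearPairs$weight
  gammaB <- if (nNl) nonlinearPairs$weight + delta else numeric()
  gammaMax <- pmax(abs(gammaA), abs(gammaB))
  tcs <- vector("list", 2L * nPerGroup)
  for (s in seq_along(tcs)) {
    set.seed(subSeeds[s])
    gamma <- if (groups[s] == "A") gammaA else gammaB
    comp <- sqrt(gammaMax^2 - gamma^2)
    tcs[[s]] <- .simulateSubject(T_, C, linearPairs, nonlinearPairs$i,
                                 nonlinearPairs$j, gamma, comp, noiseSd,
                                 arCoefficient)
  }
  new("FncCohort", timecourses = tcs, subjectId = ids, group = groups,
      componentLabels = sprintf("C%02d", seq_len(C)),
      domains = as.character(componentDomains))
}

## consecutive within-domain pairs, lambda = 0.5
.defaultLinearPairs <- function(domains) {
  i <- j <- integer()
  for (d in unique(domains)) {
    idx <- which(domains == d)
    if (length(idx) > 1L) {
      i <- c(i, idx[-length(idx)])
      j <- c(j, idx[-1L])
    }
  }
  data.frame(i = i, j = j, weight = rep(0.5, length(i)))
}

.checkPairs <- function(pairs, C) {
  need <- c("i", "j", "weight")
  if (!all(need %in% names(pairs)))
    stop("coupling tables need columns i, j, weight")
  if (nrow(pairs) == 0L) return(invisible(TRUE))
  if (any(pairs$i < 1 | pairs$i > C | pairs$j < 1 | pairs$j > C))
    stop("coupling indices out of range")
  if (any(pairs$i == pairs$j)) stop("couplings must join distinct components")
  invisible(TRUE)
}

.simulateSubject <- function(T_, C, linearPairs, nlI, nlJ, gamma, gammaComp,
                             noiseSd, ar) {
  m <- matrix(stats::rnorm(T_ * C, 0, noiseSd), T_, C)
  for (r in seq_len(nrow(linearPairs))) {
    u <- stats::rnorm(T_)
    w <- linearPairs$weight[r]
    m[, linearPairs$i[r]] <- m[, linearPairs$i[r]] + w * u
    m[, linearPairs$j[r]] <- m[, linearPairs$j[r]] + w * u
  }
  stdsq <- function(v) { q <- v^2; (q - mean(q)) / stats::sd(q) }
  for (r in seq_along(gamma)) {
    if (gamma[r] == 0 && gammaComp[r] == 0) next
    u <- stats::rnorm(T_)
    ## compensation noise is type-matched (Gaussian on the factor side,
    ## squared-Gaussian on the quadratic side) so the components' marginal
    ## distributions stay comparable across groups
    m[, nlI[r]] <- m[, nlI[r]] + gamma[r] * u +
      gammaComp[r] * stats::rnorm(T_)
    m[, nlJ[r]] <- m[, nlJ[r]] + gamma[r] * stdsq(u) +
      gammaComp[r] * stdsq(stats::rnorm(T_))
  }
  if (ar != 0)
    m <- apply(m, 2L, function(col)
      as.numeric(stats::filter(col, ar, method = "recursive")))
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}
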