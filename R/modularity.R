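#' Permutation test of domain-block structure
#'
#' Quantifies whether a mean connectivity matrix is organized by the given
#' component domains. The statistic is the mean of within-domain
#' off-diagonal cells minus the mean of between-domain cells; the null
#' distribution is built by permuting the domain labels over components,
#' and the one-sided p value is
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @param meanMatrix an [FncMatrix-class] (typically a group mean).
#' @param domains character vector assigning each component to a domain
#'   (>= 2 distinct domains, each with at least one within-domain pair
#'   overall).
#' @param nPerm number of permutations (>= 100; default 5000).
#' @param seed optional integer seed.
#' @return a [ModularityResult-class].
#' @export
blockModularityTest <- function(meanMatrix, domains, nPerm = 5000,
                                seed = NULL) {
  v <- connValues(meanMatrix)
  C <- nrow(v)
  if (length(domains) != C)
    stop("domains must have one entry per component")
  if (length(unique(domains)) < 2L) stop("need at least 2 domains")
  if (nPerm < 100) stop("nPerm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(v)
  vals <- v[ut]
  stat <- function(dom) {
    same <- outer(dom, dom, `==`)[ut]
    if (!any(same) || all(same)) return(NA_real_)
    mean(vals[same]) - mean(vals[!same])
  }
  observed <- stat(domains)
  if (is.na(observed)) stop("domain assignment yields no within/between split")
  null <- vapply(seq_len(nPerm), function(i) stat(sample(domains)),
                 numeric(1))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  new("ModularityResult", observed = observed, nullDistribution = null,
      pValue = p)
}
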