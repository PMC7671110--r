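#' Lineage-through-time profile of an ultrametric tree
#'
#' Internal node ages (root first) and the internode durations `g_k` during
#' which `k = 2, ..., n` reconstructed lineages exist. Polytomies are
#' resolved as simultaneous divergences, contributing zero-duration
#' intervals (with a warning).
#'
#' @param tree a [Chronogram-class] or ultrametric `phylo`.
#' @return a list with `ages` (internal node ages, descending, length
#'   `n - 1`), `g` (internode durations for `k = 2:n`), and `n` (tip
#'   count). `sum(g)` equals the tree height.
#' @export
lttProfile <- function(tree) {
  phy <- .phy(tree)
  n <- length(phy$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  ages <- .internalAgesMult(phy, warn.polytomy = TRUE)
  a <- sort(ages, decreasing = TRUE)
  m <- length(a)
  g <- c(a[-m] - a[-1L], a[m])
  list(ages = a, g = g, n = n)
}

#' Gamma statistic of tree shape
#'
#' The constant-rates test statistic of the lineage-through-time sequence:
#' with internode durations `g_j` while `j` lineages exist and total
#' lineage-time `T* = sum_{j=2}^{n} j g_j`,
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{k=2}^{i} k g_k -
#'   T^*/2}{T^* \sqrt{1/(12(n-2))}}}
#' Positive values indicate internal nodes concentrated toward the tips,
#' negative values toward the root; under a constant-rate pure-birth
#' process gamma is asymptotically standard normal.
#'
#' @param tree a [Chronogram-class] or ultrametric `phylo` with at least
#'   3 tips.
#' @return the gamma statistic (finite numeric).
#' @examples
#' gammaStatistic(ape::read.tree(text = "((A:1,B:1):1,C:2);"))  # -0.3464
#' @export
gammaStatistic <- function(tree) {
  phy <- .phy(tree)
  n <- length(phy$tip.label)
  if (n < 3L) stop("gamma is undefined for fewer than 3 tips")
  .gammaFromAges(.internalAgesMult(phy, warn.polytomy = TRUE))
}
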