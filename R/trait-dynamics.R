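#' Phylogenetic independent contrasts of a continuous trait
#'
#' Standardized contrasts by post-order pruning: at each internal node the
#' difference of the two daughter values is divided by the square root of
#' the summed (extension-adjusted) branch lengths, and the daughter branch
#' feeding upward is extended by `vL * vR / (vL + vR)`. Tips without trait
#' values are pruned first (with a warning); polytomies are an error —
#' resolve them before calling.
#'
#' @param tree a [Chronogram-class] or `phylo` (bifurcating).
#' @param traits named numeric vector of trait values (names are tip
#'   labels); values are used as given — log-transform body sizes before
#'   calling if appropriate.
#' @return numeric vector of `n - 1` standardized contrasts.
#' @export
independentContrasts <- function(tree, traits) {
  pt <- .pruneToTraits(tree, traits)
  if (!ape::is.binary(pt$phy))
    stop("tree contains polytomies; resolve them before computing contrasts")
  unname(ape::pic(pt$x, pt$phy))
}

.pruneToTraits <- function(tree, traits) {
  phy <- .phy(tree)
  if (is.null(names(traits))) stop("'traits' must be named by tip label")
  traits <- traits[is.finite(traits)]
  keep <- intersect(phy$tip.label, names(traits))
  if (length(keep) < 3L) stop("fewer than 3 tips with trait values")
  if (length(keep) < length(phy$tip.label)) {
    warning(sprintf("%d tip(s) without trait values pruned",
                    length(phy$tip.label) - length(keep)))
    phy <- ape::keep.tip(phy, keep)
  }
  list(phy = phy, x = traits[phy$tip.label])
}

#' Brownian-motion rate as the mean squared independent contrast
#'
#' @inheritParams independentContrasts
#' @return mean of the squared standardized contrasts (trait^2 units per
#'   unit time).
#' @export
evolutionaryRate <- function(tree, traits) {
  mean(independentContrasts(tree, traits)^2)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the lambda-transformed Brownian model: trait covariance
#' `sigma2 * C(lambda)` where `C(lambda)` rescales the off-diagonal
#' (shared-path) entries of the Brownian covariance by `lambda`, leaving
#' tip variances exact. The root state and rate are profiled out by
#' generalized least squares and `lambda` is maximized on `[0, 1]` by
#' bounded scalar search (tolerance 1e-6) with explicit endpoint checks.
#'
#' @inheritParams independentContrasts
#' @param tree a [Chronogram-class] or `phylo`.
#' @return a list with `lambda` (MLE in `[0, 1]`), `loglik` (maximized
#'   log-likelihood), `sigma2` (profiled rate at the MLE) and
#'   `identifiable` (`FALSE` when the likelihood is flat in lambda, e.g.
#'   on a star tree, in which case `lambda` is `NA`).
#' @export
pagelLambda <- function(tree, traits) {
  pt <- .pruneToTraits(tree, traits)
  x <- pt$x
  n <- length(x)
  if (sd(x) == 0)
    return(list(lambda = NA_real_, loglik = NA_real_, sigma2 = 0,
                identifiable = FALSE))
  C <- ape::vcv(pt$phy)
  profile <- function(lam) {
    V <- C * lam
    diag(V) <- diag(C)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = Inf))
    logdet <- 2 * sum(log(diag(ch)))
    z <- backsolve(ch, cbind(x, rep(1, n)), transpose = TRUE)
    xiVx <- sum(z[, 1L]^2); xiV1 <- sum(z[, 1L] * z[, 2L])
    oiV1 <- sum(z[, 2L]^2)
    a <- xiV1 / oiV1
    q <- xiVx - 2 * a * xiV1 + a^2 * oiV1
    s2 <- q / n
    if (s2 <= 0) return(list(nll = Inf))
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
    list(nll = -ll, sigma2 = s2)
  }
  opt <- optimize(function(l) profile(l)$nll, c(0, 1), tol = 1e-6)
  cand <- c(0, opt$minimum, 1)
  nll <- vapply(cand, function(l) profile(l)$nll, numeric(1))
  best <- which.min(nll)
  # flat likelihood (e.g. star tree): lambda not identifiable
  if (max(nll[is.finite(nll)]) - min(nll[is.finite(nll)]) < 1e-8)
    return(list(lambda = NA_real_, loglik = -nll[best],
                sigma2 = profile(cand[best])$sigma2, identifiable = FALSE))
  list(lambda = cand[best], loglik = -nll[best],
       sigma2 = profile(cand[best])$sigma2, identifiable = TRUE)
}

#' Trait-evolution inferences across taxonomic history
#'
#' For each scheduled year, prunes the tree to the species described by
#' that year, restricts the trait data, and records the mean squared
#' contrast rate and the Pagel's lambda MLE. Years with fewer than 3
#' trait-bearing species are skipped.
#'
#' @param tree the full aligned [Chronogram-class].
#' @param table the aligned [TaxonomyTable-class].
#' @param traits named numeric trait vector; defaults to the table's
#'   `trait` column when present.
#' @param schedule a [SliceSchedule-class].
#' @return a [TraitSeries-class] with columns `year`, `n_trait_tips`,
#'   `rate_msq_contrast`, `lambda_hat`, `loglik`.
#' @export
traitSeries <- function(tree, table, traits = NULL, schedule) {
  cg <- .chronogram(tree)
  df <- as.data.frame(table)
  if (is.null(traits)) {
    traits <- traitValues(table)
    if (is.null(traits)) stop("no trait values given and table has no trait column")
  }
  traits <- traits[is.finite(traits)]
  rows <- list()
  for (y in scheduleYears(schedule)) {
    known <- df$species[df$year <= y]
    withTrait <- intersect(known, names(traits))
    if (length(withTrait) < 3L) next
    pruned <- suppressWarnings(pruneToYear(cg, table, y))
    tr <- traits[withTrait]
    rate <- suppressWarnings(evolutionaryRate(pruned, tr))
    lam <- suppressWarnings(pagelLambda(pruned, tr))
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, n_trait_tips = length(withTrait),
      rate_msq_contrast = rate, lambda_hat = lam$lambda,
      loglik = lam$loglik)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(year = integer(0), n_trait_tips = integer(0),
               rate_msq_contrast = numeric(0), lambda_hat = numeric(0),
               loglik = numeric(0))
  new("TraitSeries", table = tab)
}
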