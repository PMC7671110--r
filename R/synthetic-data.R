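#' Simulate a birth-death chronogram conditioned on tip count
#'
#' Constant-rate birth-death simulation conditioned on the number of
#' extant tips (extinct lineages pruned), via [ape::rphylo()]. Optionally
#' rescales the tree to unit height, which puts node ages on a relative
#' 0-1 scale — convenient when a discovery-bias strength must be
#' comparable across trees.
#'
#' @param nTips number of extant tips (>= 3).
#' @param birth,death per-lineage rates, `birth > death >= 0`.
#' @param seed integer seed or `NULL`.
#' @param scaleHeight rescale branch lengths so the height is 1 (default
#'   `FALSE`).
#' @return a [Chronogram-class] with tips `t1 ... tn`.
#' @export
simulateTree <- function(nTips, birth = 1, death = 0, seed = NULL,
                         scaleHeight = FALSE) {
  nTips <- as.integer(nTips)
  if (nTips < 3L) stop("nTips must be >= 3")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  .setSeed(seed)
  phy <- ape::rphylo(nTips, birth = birth, death = death, fossils = FALSE)
  if (scaleHeight) {
    h <- max(.tipDepths(phy))
    phy$edge.length <- phy$edge.length / h
  }
  Chronogram(phy, tolerance = 1e-6)
}

#' Assign description years to the tips of a chronogram
#'
#' Draws a description order under the given [DiscoveryModel-class], then
#' maps order positions to integer years across the model's range by the
#' per-year intensity profile (constant by default, linear ramp optional).
#'
#' Orders: `uniform` is a uniform random permutation. `depth_biased` picks
#' species sequentially without replacement with weight
#' `exp(beta * a_s)`, where the attachment age `a_s` is the age at which
#' species `s` diverges from its closest already-picked species (for the
#' first pick, the distance to the root, equal for all tips of an
#' ultrametric tree); ages are recomputed against the growing picked set,
#' so the bias acts on the same quantity as the added-branch-length
#' metric. `trait_biased` uses fixed weights `exp(beta * z_s)` for the
#' standardized trait.
#'
#' @param tree a [Chronogram-class].
#' @param model a [DiscoveryModel-class].
#' @param seed integer seed or `NULL`.
#' @param traits named numeric vector, required for `trait_biased`.
#' @return a [TaxonomyTable-class] with one row per tip.
#' @export
assignYears <- function(tree, model, seed = NULL, traits = NULL) {
  cg <- .chronogram(tree)
  phy <- cg@tree
  n <- length(phy$tip.label)
  .setSeed(seed)
  ord <- switch(model@kind,
    uniform = sample.int(n),
    depth_biased = .depthBiasedOrder(phy, model@beta),
    trait_biased = {
      if (is.null(traits)) stop("trait_biased model needs 'traits'")
      z <- traits[phy$tip.label]
      if (anyNA(z)) stop("traits must cover every tip")
      z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
      w <- exp(model@beta * (z - max(z)))
      sample.int(n, prob = w)
    })
  years <- .allocateYears(n, model@startYear, model@endYear, model@ramp)
  df <- data.frame(species = phy$tip.label[ord], year = years,
                   stringsAsFactors = FALSE)
  df <- df[match(phy$tip.label, df$species), , drop = FALSE]
  rownames(df) <- NULL
  suppressWarnings(TaxonomyTable(df))
}

# sequential sampling without replacement, weight exp(beta * attachment
# age); attachment ages against the picked set are maintained as the
# running maximum shared depth with any picked tip
.depthBiasedOrder <- function(phy, beta) {
  n <- length(phy$tip.label)
  if (beta == 0) return(sample.int(n))
  v <- ape::vcv(phy)
  h <- max(diag(v))
  picked <- integer(n)
  remaining <- seq_len(n)
  maxShared <- rep(0, n)          # max shared depth with the picked set
  for (i in seq_len(n)) {
    a <- h - maxShared[remaining] # attachment ages (first pick: root age)
    w <- exp(beta * (a - max(a)))
    pick <- remaining[sample.int(length(remaining), 1L, prob = w)]
    picked[i] <- pick
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      maxShared[remaining] <- pmax(maxShared[remaining], v[remaining, pick])
  }
  picked
}

# spread N descriptions over [start, end] proportionally to a linearly
# ramped intensity; returns the year of the i-th described species
.allocateYears <- function(n, start, end, ramp = 0) {
  yrs <- start:end
  k <- length(yrs)
  w <- 1 + ramp * (seq_len(k) - 1) / max(k - 1, 1)
  counts <- diff(c(0L, round(cumsum(w) / sum(w) * n)))
  rep(yrs, counts)
}

#' Simulate a continuous trait under lambda-transformed Brownian motion
#'
#' Draws one exact multivariate-normal sample with covariance
#' `sigma2 * C(lambda)`, where `C(lambda)` is the Brownian covariance of
#' the tree with off-diagonal entries scaled by `lambda` (tip variances
#' exact). Exact covariance sampling, not recursive simulation, so
#' `lambda != 1` traits follow the model exactly.
#'
#' @param tree a [Chronogram-class].
#' @param sigma2 Brownian rate (>= 0), trait^2 units per unit time.
#' @param lambda phylogenetic signal in `[0, 1]`.
#' @param root root (mean) state.
#' @param seed integer seed or `NULL`.
#' @return named numeric vector, one value per tip.
#' @export
simulateTrait <- function(tree, sigma2, lambda = 1, root = 0, seed = NULL) {
  cg <- .chronogram(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  phy <- cg@tree
  n <- length(phy$tip.label)
  .setSeed(seed)
  if (sigma2 == 0)
    return(setNames(rep(root, n), phy$tip.label))
  C <- ape::vcv(phy)
  V <- C * lambda
  diag(V) <- diag(C)
  x <- root + as.vector(MASS::mvrnorm(1L, mu = rep(0, n), Sigma = sigma2 * V))
  setNames(x, phy$tip.label)
}

#' Write a ready-to-run synthetic fixture (tree + taxonomy TSV)
#'
#' Simulates a chronogram, a description history and (optionally) a trait,
#' and writes `tree.nwk` and `taxonomy.tsv` into `dir` in the same formats
#' the analysis functions consume.
#'
#' @param dir output directory (created if needed).
#' @param nTips,birth,death passed to [simulateTree()] (height is
#'   normalised to 1).
#' @param model a [DiscoveryModel-class].
#' @param sigma2 if non-`NULL`, also simulate a trait at this rate with
#'   `traitLambda` and include it as a `trait` column.
#' @param traitLambda lambda for the simulated trait.
#' @param seed root seed; tree, years and trait use seeds spawned from it.
#' @return named character vector of the written paths, invisibly.
#' @export
simulateFixture <- function(dir, nTips = 200L, birth = 1, death = 0,
                            model = discoveryModel("uniform"),
                            sigma2 = NULL, traitLambda = 1, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .spawnSeeds(seed, 3L)
  cg <- simulateTree(nTips, birth, death, seed = seeds[1L],
                     scaleHeight = TRUE)
  tr <- if (!is.null(sigma2))
    simulateTrait(cg, sigma2, traitLambda, seed = seeds[3L]) else NULL
  tab <- assignYears(cg, model, seed = seeds[2L], traits = tr)
  df <- as.data.frame(tab)
  if (!is.null(tr)) df$trait <- unname(tr[df$species])
  treePath <- file.path(dir, "tree.nwk")
  taxPath <- file.path(dir, "taxonomy.tsv")
  writeChronogram(cg, treePath)
  .writeTsv(df, taxPath)
  invisible(c(tree = treePath, taxonomy = taxPath))
}
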