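#' @import methods
#' @importFrom stats quantile runif lm coef optimize sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

setOldClass("phylo")

#' Chronogram: a rooted ultrametric time-calibrated phylogeny
#'
#' Thin S4 wrapper around an [ape::read.tree()] `phylo` object that has been
#' validated as a chronogram: rooted, branch lengths in time units, all tips
#' equidistant from the root (within a relative tolerance), unique tip
#' labels, non-negative branch lengths and at least two tips.
#'
#' @slot tree the underlying `phylo` object.
#' @slot height tree height (mean root-to-tip path length), in the tree's
#'   time units.
#' @slot tolerance the accepted relative deviation from ultrametricity
#'   (maximum |root-to-tip distance - height| / height).
#' @seealso [readChronogram()], [asPhylo()], [treeHeight()]
#' @exportClass Chronogram
setClass("Chronogram",
         representation(tree = "phylo", height = "numeric",
                        tolerance = "numeric"))

setValidity("Chronogram", function(object) {
  phy <- object@tree
  msgs <- character()
  if (is.null(phy$edge.length))
    msgs <- c(msgs, "tree has no branch lengths")
  n <- length(phy$tip.label)
  if (n < 2) msgs <- c(msgs, "chronogram needs at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    msgs <- c(msgs, "tip labels are not unique")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    msgs <- c(msgs, "negative branch length")
  if (length(msgs) == 0L) {
    d <- .tipDepths(phy)
    h <- mean(d)
    dev <- if (h > 0) max(abs(d - h)) / h else 0
    if (dev > object@tolerance + 1e-12)
      msgs <- c(msgs, sprintf(
        "tree is not ultrametric: relative deviation %.3g exceeds tolerance %.3g",
        dev, object@tolerance))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Chronogram from a phylo object
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param tolerance relative ultrametricity tolerance (default `1e-6` times
#'   the tree height).
#' @param strict if `TRUE` (default) a tree whose root-to-tip distances vary
#'   by more than `tolerance` is an error; if `FALSE` the deviation is
#'   reported as a warning and accepted.
#' @return a [Chronogram-class] object.
#' @export
Chronogram <- function(tree, tolerance = 1e-6, strict = TRUE) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(tree)) stop("chronogram must be rooted")
  d <- .tipDepths(tree)
  h <- mean(d)
  dev <- if (h > 0) max(abs(d - h)) / h else 0
  tol <- tolerance
  if (dev > tolerance) {
    if (strict)
      stop(sprintf(
        "tree is not ultrametric: max relative root-to-tip deviation %.3g (tolerance %.3g)",
        dev, tolerance))
    warning(sprintf(
      "tree accepted despite ultrametricity deviation %.3g (lenient mode); ages near the tips may be unreliable",
      dev))
    tol <- dev * (1 + 1e-9)
  }
  new("Chronogram", tree = tree, height = h, tolerance = tol)
}

#' TaxonomyTable: species description years (plus optional group and trait)
#'
#' @slot data a `data.frame` with columns `species` (character, unique),
#'   `year` (integer) and optionally `group` (character) and `trait`
#'   (numeric).
#' @seealso [readTaxonomy()], [descriptionYears()]
#' @exportClass TaxonomyTable
setClass("TaxonomyTable", representation(data = "data.frame"))

setValidity("TaxonomyTable", function(object) {
  df <- object@data
  msgs <- character()
  if (nrow(df) == 0L) msgs <- c(msgs, "taxonomy table is empty")
  if (!all(c("species", "year") %in% names(df)))
    msgs <- c(msgs, "taxonomy table needs 'species' and 'year' columns")
  else {
    if (anyDuplicated(df$species))
      msgs <- c(msgs, sprintf("duplicated species: %s",
                              paste(unique(df$species[duplicated(df$species)]),
                                    collapse = ", ")))
    if (!is.integer(df$year) || anyNA(df$year))
      msgs <- c(msgs, "'year' must be finite integers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxonomyTable from a data frame
#'
#' Years earlier than 1758 (the starting point of zoological nomenclature;
#' botanical names begin in 1753) are accepted with a warning.
#'
#' @param data a data frame with columns `species` and `year`, and
#'   optionally `group` and `trait`.
#' @return a [TaxonomyTable-class] object.
#' @export
TaxonomyTable <- function(data) {
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!all(c("species", "year") %in% names(df)))
    stop("taxonomy data needs 'species' and 'year' columns")
  df$species <- as.character(df$species)
  yr <- df$year
  if (!is.integer(yr)) {
    ok <- is.finite(suppressWarnings(as.numeric(yr))) &
      suppressWarnings(as.numeric(yr)) == round(suppressWarnings(as.numeric(yr)))
    ok[is.na(ok)] <- FALSE
    if (!all(ok))
      stop(sprintf("non-integer year in row(s): %s",
                   paste(which(!ok), collapse = ", ")))
    df$year <- as.integer(round(as.numeric(yr)))
  }
  if (any(df$year < 1758))
    warning(sprintf("%d description year(s) earlier than 1758",
                    sum(df$year < 1758)))
  new("TaxonomyTable", data = df)
}

#' AlignmentReport: record of tips and records dropped during alignment
#'
#' @slot droppedTips tree tips without a description year (pruned).
#' @slot droppedRecords taxonomy records not present in the tree (removed).
#' @exportClass AlignmentReport
setClass("AlignmentReport",
         representation(droppedTips = "character",
                        droppedRecords = "character"))

#' SliceSchedule: years at which the historical phylogeny is evaluated
#'
#' @slot years strictly increasing integer evaluation years; the first is
#'   the minimum start year (the year the third species was described) and
#'   the last the final description year.
#' @slot step step between consecutive evaluation years (years).
#' @slot window trailing window (years) used for the branch-length pool and
#'   interval phylogenetic diversity.
#' @slot startYear first evaluation year.
#' @slot finalYear last description year.
#' @exportClass SliceSchedule
setClass("SliceSchedule",
         representation(years = "integer", step = "integer",
                        window = "integer", startYear = "integer",
                        finalYear = "integer"))

setValidity("SliceSchedule", function(object) {
  y <- object@years
  msgs <- character()
  if (length(y) < 1L) msgs <- c(msgs, "empty schedule")
  if (length(y) > 1L && any(diff(y) <= 0L))
    msgs <- c(msgs, "years must be strictly increasing")
  if (length(y) >= 1L && y[1L] != object@startYear)
    msgs <- c(msgs, "first year must equal the start year")
  if (length(y) >= 1L && y[length(y)] != object@finalYear)
    msgs <- c(msgs, "last year must equal the final described year")
  if (length(msgs)) msgs else TRUE
})

#' MetricTrajectory: per-slice tree-shape metrics across taxonomic history
#'
#' One row per evaluation year with the tip count, the pooled branch
#' lengths added over the trailing window (mean/max/min), the gamma
#' statistic with its random-pruning null band, observed-minus-expected
#' gamma, and the phylogenetic diversity of the window's new species.
#'
#' @slot table the trajectory `data.frame` (see [metricTrajectory()] for
#'   columns).
#' @slot window trailing window in years.
#' @slot nullReps replicates used for each per-slice null.
#' @slot seed the seed used, or `NA`.
#' @exportClass MetricTrajectory
setClass("MetricTrajectory",
         representation(table = "data.frame", window = "integer",
                        nullReps = "integer", seed = "integer"))

#' GammaNull: random-pruning null distribution for the gamma statistic
#'
#' @slot replicates gamma of each randomly pruned replicate tree.
#' @slot mean mean of the replicates (the "expected" gamma).
#' @slot lower,upper 2.5% and 97.5% percentiles (linear interpolation
#'   between order statistics).
#' @slot nMissing number of tips removed in each replicate.
#' @slot seed seed used, or `NA`.
#' @exportClass GammaNull
setClass("GammaNull",
         representation(replicates = "numeric", mean = "numeric",
                        lower = "numeric", upper = "numeric",
                        nMissing = "integer", seed = "integer"))

setValidity("GammaNull", function(object) {
  if (length(object@replicates) >= 2 &&
      !(object@lower <= object@mean + 1e-12 &&
        object@mean <= object@upper + 1e-12))
    "percentiles must bracket the mean" else TRUE
})

#' GammaForecast: distribution of gamma after random tip addition
#'
#' @slot replicates gamma of each augmented tree.
#' @slot nAdd number of tips grafted per replicate.
#' @slot sourceYear knowledge year of the source tree (`NA` if not given).
#' @slot lower,upper 2.5% and 97.5% percentiles of the replicates.
#' @slot seed seed used, or `NA`.
#' @slot trees augmented `phylo` trees when requested (else empty list).
#' @exportClass GammaForecast
setClass("GammaForecast",
         representation(replicates = "numeric", nAdd = "integer",
                        sourceYear = "integer", lower = "numeric",
                        upper = "numeric", seed = "integer",
                        trees = "list"))

#' TraitSeries: trait-evolution inferences across taxonomic history
#'
#' @slot table a `data.frame` with columns `year`, `n_trait_tips`,
#'   `rate_msq_contrast`, `lambda_hat`, `loglik`.
#' @exportClass TraitSeries
setClass("TraitSeries", representation(table = "data.frame"))

#' DiscoveryModel: how description order relates to the phylogeny
#'
#' Defines the generator for synthetic description histories: `uniform`
#' (order is a uniform permutation), `depth_biased` (species with older
#' attachment ages relative to the already-described set are described
#' first, weight proportional to `exp(beta * age)`), or `trait_biased`
#' (weight proportional to `exp(beta * z)` for the standardized trait).
#'
#' @slot kind one of `"uniform"`, `"depth_biased"`, `"trait_biased"`.
#' @slot beta bias strength (>= 0); `beta = 0` reduces both biased models
#'   to `uniform`.
#' @slot startYear,endYear year range over which descriptions are spread.
#' @slot ramp linear ramp of the per-year description intensity: 0 is
#'   constant; with ramp `r` the final year is `1 + r` times as intense as
#'   the first.
#' @seealso [discoveryModel()], [assignYears()]
#' @exportClass DiscoveryModel
setClass("DiscoveryModel",
         representation(kind = "character", beta = "numeric",
                        startYear = "integer", endYear = "integer",
                        ramp = "numeric"))

setValidity("DiscoveryModel", function(object) {
  msgs <- character()
  if (!object@kind %in% c("uniform", "depth_biased", "trait_biased"))
    msgs <- c(msgs, "unknown discovery model kind")
  if (object@beta < 0) msgs <- c(msgs, "beta must be >= 0")
  if (object@endYear < object@startYear)
    msgs <- c(msgs, "endYear must be >= startYear")
  if (object@ramp < -1) msgs <- c(msgs, "ramp must be >= -1")
  if (length(msgs)) msgs else TRUE
})

#' Specify a discovery model for synthetic description histories
#'
#' @param kind `"uniform"`, `"depth_biased"` or `"trait_biased"`.
#' @param beta bias strength; 0 gives a uniform order for every kind.
#' @param startYear,endYear inclusive year range of descriptions.
#' @param ramp linear intensity ramp (0 = constant species/year).
#' @return a [DiscoveryModel-class] object.
#' @export
discoveryModel <- function(kind = c("uniform", "depth_biased", "trait_biased"),
                           beta = 0, startYear = 1758L, endYear = 2019L,
                           ramp = 0) {
  kind <- match.arg(kind)
  new("DiscoveryModel", kind = kind, beta = as.numeric(beta),
      startYear = as.integer(startYear), endYear = as.integer(endYear),
      ramp = as.numeric(ramp))
}
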