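#' Branch lengths added by newly described species in an interval
#'
#' For each species described in `(yearPrev, yearNow]`, returns its pendant
#' edge length in the tree as known at `yearNow`. For an ultrametric tree
#' this equals the species' attachment age: the age at which its lineage
#' diverges from the closest species already known by `yearNow`.
#'
#' @param tree a [Chronogram-class] aligned with `table`.
#' @param table a [TaxonomyTable-class].
#' @param yearPrev,yearNow interval bounds, `yearPrev < yearNow`. Use
#'   `yearPrev = -Inf` for the first slice, where every species known at
#'   `yearNow` counts as new.
#' @return a list with `lengths` (named numeric, possibly empty), and
#'   `mean`, `max`, `min` (`NA` when the interval added no species).
#' @export
addedBranchLengths <- function(tree, table, yearPrev, yearNow) {
  if (!(yearPrev < yearNow)) stop("yearPrev must be < yearNow")
  df <- as.data.frame(table)
  newSp <- df$species[df$year > yearPrev & df$year <= yearNow]
  if (length(newSp) == 0L)
    return(list(lengths = setNames(numeric(0), character(0)),
                mean = NA_real_, max = NA_real_, min = NA_real_))
  pruned <- pruneToYear(tree, table, yearNow)
  lens <- .pendantLengths(pruned@tree, newSp)
  list(lengths = lens, mean = mean(lens), max = max(lens), min = min(lens))
}

.pendantLengths <- function(phy, species) {
  idx <- match(species, phy$tip.label)
  if (anyNA(idx))
    stop(sprintf("species not in pruned tree: %s",
                 paste(species[is.na(idx)], collapse = ", ")))
  pos <- match(idx, phy$edge[, 2])
  setNames(phy$edge.length[pos], species)
}

#' Rooted phylogenetic diversity of a species set
#'
#' Summed branch lengths of the subtree spanning the given species and the
#' root of the full tree (rooted Faith PD). The root path is retained —
#' the convention obtained by pruning the full tree down to the set and
#' summing all remaining branch lengths — which also makes singleton sets
#' well defined (PD = distance from the tip to the root).
#'
#' @param tree the full [Chronogram-class] or `phylo`.
#' @param species character vector of tip labels (non-empty).
#' @return summed branch length (time units).
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylogeneticDiversity(phy, c("B", "C"))  # 4
#' @export
phylogeneticDiversity <- function(tree, species) {
  phy <- .phy(tree)
  if (length(species) == 0L) stop("species set is empty")
  idx <- match(species, phy$tip.label)
  if (anyNA(idx))
    stop(sprintf("unknown species: %s",
                 paste(species[is.na(idx)], collapse = ", ")))
  po <- ape::reorder.phylo(phy, "postorder")
  inSet <- logical(length(phy$tip.label) + phy$Nnode)
  inSet[idx] <- TRUE
  total <- 0
  for (i in seq_len(nrow(po$edge))) {
    child <- po$edge[i, 2L]
    if (inSet[child]) {
      total <- total + po$edge.length[i]
      inSet[po$edge[i, 1L]] <- TRUE
    }
  }
  total
}

#' Per-slice tree-shape metrics across taxonomic history
#'
#' For every year of the schedule, evaluates the historical tree (all
#' species described by that year) and records: the gamma statistic with a
#' random-pruning null distribution from the full tree (same number of
#' missing species; see [gammaNull()]), observed-minus-expected gamma
#' (`gamma_oe`), the pendant branch lengths added over the trailing
#' `window` years pooled and summarised (mean/max/min), and the rooted
#' phylogenetic diversity of the window's newly described species measured
#' on the full tree. At the first slice all species known by the start
#' year count as newly added. Windows that add no species yield missing
#' values, not zeros.
#'
#' @param tree the full aligned [Chronogram-class].
#' @param table the aligned [TaxonomyTable-class].
#' @param schedule a [SliceSchedule-class] from [sliceSchedule()].
#' @param window trailing window in years (default: the schedule's).
#' @param nullReps replicates per per-slice gamma null (default 1000).
#' @param seed integer seed controlling all null replicates (one root seed;
#'   per-slice seeds are spawned from it), or `NULL`.
#' @return a [MetricTrajectory-class]; its table has columns `year`,
#'   `n_tips`, `n_added_window`, `bl_mean`, `bl_max`, `bl_min`, `gamma`,
#'   `gamma_null_mean`, `gamma_null_p2_5`, `gamma_null_p97_5`, `gamma_oe`,
#'   `pd_window`.
#' @export
metricTrajectory <- function(tree, table, schedule, window = NULL,
                             nullReps = 1000L, seed = NULL) {
  cg <- .chronogram(tree)
  df <- as.data.frame(table)
  if (!setequal(df$species, cg@tree$tip.label))
    stop("tree and taxonomy must be aligned (identical species sets)")
  if (is.null(window)) window <- schedule@window
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  years <- scheduleYears(schedule)
  N <- nSpecies(cg)
  sliceSeeds <- .spawnSeeds(seed, length(years))
  ctx <- .sliceContext(cg@tree)

  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    y <- years[i]
    known <- df$species[df$year <= y]
    ny <- length(known)
    pruned <- pruneToYear(cg, table, y)
    gam <- gammaStatistic(pruned)
    null <- gammaNull(cg, nMissing = N - ny, reps = nullReps,
                      seed = sliceSeeds[i], context = ctx)
    lo <- if (i == 1L) -Inf else y - window
    newSp <- df$species[df$year > lo & df$year <= y]
    if (length(newSp)) {
      lens <- .pendantLengths(pruned@tree, newSp)
      blMean <- mean(lens); blMax <- max(lens); blMin <- min(lens)
      pd <- phylogeneticDiversity(cg, newSp)
    } else {
      blMean <- blMax <- blMin <- pd <- NA_real_
    }
    rows[[i]] <- data.frame(
      year = y, n_tips = ny, n_added_window = length(newSp),
      bl_mean = blMean, bl_max = blMax, bl_min = blMin,
      gamma = gam, gamma_null_mean = null@mean,
      gamma_null_p2_5 = null@lower, gamma_null_p97_5 = null@upper,
      gamma_oe = gammaOE(gam, null), pd_window = pd)
  }
  new("MetricTrajectory", table = do.call(rbind, rows),
      window = window, nullReps = as.integer(nullReps),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Write a metric trajectory as TSV
#'
#' @param x a [MetricTrajectory-class] or [TraitSeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(x, path) .writeTsv(as.data.frame(x), path)
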