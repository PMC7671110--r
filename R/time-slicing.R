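#' Minimum start year of a taxonomic history
#'
#' The first year at which the historical tree contains at least three
#' species, i.e. the year the third species was described (with ties, the
#' year at which the cumulative described count first reaches 3).
#'
#' @param table a [TaxonomyTable-class].
#' @return integer year.
#' @export
minimumStartYear <- function(table) {
  yr <- sort(as.data.frame(table)$year)
  if (length(yr) < 3L)
    stop("need at least 3 described species to start a history")
  yr[3L]
}

#' Prune a chronogram to the species known in a given year
#'
#' Returns the tree containing exactly the species described in or before
#' `year`. Unifurcations created by the pruning are suppressed with edge
#' lengths summed, so retained root-to-tip distances are unchanged; if the
#' original root has a single surviving child lineage the new root is the
#' first surviving bifurcation (standard drop-tip semantics).
#'
#' @param tree a [Chronogram-class] aligned with `table`.
#' @param table a [TaxonomyTable-class].
#' @param year integer evaluation year.
#' @return the pruned [Chronogram-class].
#' @export
pruneToYear <- function(tree, table, year) {
  cg <- .chronogram(tree)
  df <- as.data.frame(table)
  missing <- setdiff(df$species, cg@tree$tip.label)
  if (length(missing))
    stop(sprintf("species not in tree (align first): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  keep <- df$species[df$year <= year]
  if (length(keep) < 2L)
    stop(sprintf("fewer than 2 species described by %d", year))
  if (length(keep) == nSpecies(cg)) return(cg)
  phy <- ape::keep.tip(cg@tree, keep)
  new("Chronogram", tree = phy, height = mean(.tipDepths(phy)),
      tolerance = cg@tolerance)
}

#' Build the evaluation schedule over a taxonomic history
#'
#' Evaluation years run from the minimum start year (year of the third
#' described species) in steps of `step`; the final description year is
#' always appended if the stepping does not land on it.
#'
#' @param table a [TaxonomyTable-class].
#' @param step step between evaluation years, in years (>= 1).
#' @param window trailing window in years recorded on the schedule for
#'   downstream branch-length pooling and interval PD (default 5).
#' @return a [SliceSchedule-class].
#' @examples
#' tab <- TaxonomyTable(data.frame(
#'   species = c("A", "B", "C", "D"),
#'   year = c(1758L, 1800L, 1900L, 1953L)))
#' scheduleYears(sliceSchedule(tab, step = 5))
#' @export
sliceSchedule <- function(table, step = 1L, window = 5L) {
  step <- as.integer(step)
  if (is.na(step) || step < 1L) stop("step must be >= 1")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  start <- minimumStartYear(table)
  final <- max(as.data.frame(table)$year)
  years <- seq.int(start, final, by = step)
  if (years[length(years)] != final) years <- c(years, final)
  new("SliceSchedule", years = as.integer(years), step = step,
      window = window, startYear = as.integer(start),
      finalYear = as.integer(final))
}
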