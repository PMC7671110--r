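#' Extract the underlying phylo object
#' @param x a [Chronogram-class].
#' @return the `phylo` object.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname asPhylo
setMethod("asPhylo", "Chronogram", function(x) x@tree)

#' Tree height (root-to-tip path length) of a chronogram
#' @param x a [Chronogram-class].
#' @return numeric tree height in the tree's time units.
#' @export
setGeneric("treeHeight", function(x) standardGeneric("treeHeight"))

#' @rdname treeHeight
setMethod("treeHeight", "Chronogram", function(x) x@height)

#' Number of tips
#' @param x a [Chronogram-class] or [TaxonomyTable-class].
#' @return integer count of species.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname nSpecies
setMethod("nSpecies", "Chronogram", function(x) length(x@tree$tip.label))

#' @rdname nSpecies
setMethod("nSpecies", "TaxonomyTable", function(x) nrow(x@data))

#' Species labels
#' @param x a [Chronogram-class] or [TaxonomyTable-class].
#' @return character vector of species names.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname speciesNames
setMethod("speciesNames", "Chronogram", function(x) x@tree$tip.label)

#' @rdname speciesNames
setMethod("speciesNames", "TaxonomyTable", function(x) x@data$species)

#' Description years, named by species
#' @param x a [TaxonomyTable-class].
#' @return named integer vector.
#' @export
setGeneric("descriptionYears", function(x) standardGeneric("descriptionYears"))

#' @rdname descriptionYears
setMethod("descriptionYears", "TaxonomyTable",
          function(x) setNames(x@data$year, x@data$species))

#' Trait values stored in a taxonomy table, named by species
#' @param x a [TaxonomyTable-class].
#' @return named numeric vector, or `NULL` when no trait column is present.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname traitValues
setMethod("traitValues", "TaxonomyTable", function(x) {
  if (!"trait" %in% names(x@data)) return(NULL)
  setNames(x@data$trait, x@data$species)
})

#' Evaluation years of a slice schedule
#' @param x a [SliceSchedule-class].
#' @return integer vector of years.
#' @export
setGeneric("scheduleYears", function(x) standardGeneric("scheduleYears"))

#' @rdname scheduleYears
setMethod("scheduleYears", "SliceSchedule", function(x) x@years)

#' Replicate values of a null or forecast distribution
#' @param x a [GammaNull-class] or [GammaForecast-class].
#' @return numeric vector of per-replicate gamma values.
#' @export
setGeneric("replicateValues", function(x) standardGeneric("replicateValues"))

#' @rdname replicateValues
setMethod("replicateValues", "GammaNull", function(x) x@replicates)

#' @rdname replicateValues
setMethod("replicateValues", "GammaForecast", function(x) x@replicates)

#' @export
setMethod("as.data.frame", "TaxonomyTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @export
setMethod("as.data.frame", "MetricTrajectory",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' @export
setMethod("as.data.frame", "TraitSeries",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "Chronogram", function(object) {
  cat(sprintf("Chronogram: %d tips, height %.4g (ultrametric tol %.2g)\n",
              nSpecies(object), object@height, object@tolerance))
})

setMethod("show", "TaxonomyTable", function(object) {
  df <- object@data
  cat(sprintf("TaxonomyTable: %d species, years %d-%d%s%s\n",
              nrow(df), min(df$year), max(df$year),
              if ("group" %in% names(df)) sprintf(", %d group(s)",
                length(unique(df$group))) else "",
              if ("trait" %in% names(df)) ", with trait" else ""))
})

setMethod("show", "AlignmentReport", function(object) {
  cat(sprintf(
    "AlignmentReport: %d tip(s) without year dropped from tree, %d record(s) not in tree dropped from table\n",
    length(object@droppedTips), length(object@droppedRecords)))
})

setMethod("show", "SliceSchedule", function(object) {
  cat(sprintf("SliceSchedule: %d evaluation years (%d-%d, step %d, window %d)\n",
              length(object@years), object@startYear, object@finalYear,
              object@step, object@window))
})

setMethod("show", "MetricTrajectory", function(object) {
  cat(sprintf("MetricTrajectory: %d slices, window %d yr, %d-rep nulls\n",
              nrow(object@table), object@window, object@nullReps))
})

setMethod("show", "GammaNull", function(object) {
  cat(sprintf(
    "GammaNull: %d replicates, %d tip(s) removed; mean %.4f [%.4f, %.4f]\n",
    length(object@replicates), object@nMissing, object@mean,
    object@lower, object@upper))
})

setMethod("show", "GammaForecast", function(object) {
  cat(sprintf(
    "GammaForecast: %d replicates, %d tip(s) added; mean %.4f [%.4f, %.4f]\n",
    length(object@replicates), object@nAdd, mean(object@replicates),
    object@lower, object@upper))
})

setMethod("show", "TraitSeries", function(object) {
  cat(sprintf("TraitSeries: %d slices (years %s-%s)\n", nrow(object@table),
              if (nrow(object@table)) min(object@table$year) else "-",
              if (nrow(object@table)) max(object@table$year) else "-"))
})

setMethod("show", "DiscoveryModel", function(object) {
  cat(sprintf("DiscoveryModel: %s (beta %.3g), years %d-%d, ramp %.3g\n",
              object@kind, object@beta, object@startYear, object@endYear,
              object@ramp))
})
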