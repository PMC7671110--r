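#' Run the full taxonomic-maturation pipeline
#'
#' Reads a chronogram and a taxonomy table, aligns them, builds the
#' evaluation schedule and writes the metric trajectory (and, when
#' requested or available, the trait series and a gamma forecast) as TSV
#' files plus a plain-text log. Deterministic given `seed`: one root seed
#' drives every stochastic component through spawned sub-seeds (trajectory
#' nulls first, then the forecast).
#'
#' When the taxonomy has a `group` column and `perGroup = TRUE`, the
#' analysis is additionally repeated per group (table subset, tree
#' re-aligned), writing `trajectory_<group>.tsv` files.
#'
#' @param treeFile path to the Newick chronogram.
#' @param taxonomyFile path to the taxonomy TSV/CSV.
#' @param outDir output directory (created if needed).
#' @param step,window schedule step and trailing window, years.
#' @param nullReps replicates per per-slice gamma null (default 1000).
#' @param slopeSpan span of the recent gamma_OE slope, years (default 30).
#' @param forecastAtYear if non-`NULL`, also forecast present-day gamma
#'   from the tree as known at this year.
#' @param forecastReps forecast replicates (default 100).
#' @param traitColumn name of the taxonomy trait column to analyse
#'   (`NULL` = analyse `trait` when present).
#' @param seed root integer seed.
#' @param strict reject non-ultrametric trees (default `TRUE`).
#' @param keepReplicates also dump the forecast replicate gammas (TSV with
#'   columns `source_year`, `n_add`, `rep`, `gamma`).
#' @param perGroup repeat the trajectory per `group` value (default
#'   `TRUE` when a group column exists).
#' @return invisibly, a list with the trajectory, trait series, forecast,
#'   recent slope and the paths written.
#' @export
runPipeline <- function(treeFile, taxonomyFile, outDir,
                        step = 1L, window = 5L, nullReps = 1000L,
                        slopeSpan = 30L, forecastAtYear = NULL,
                        forecastReps = 100L, traitColumn = NULL,
                        seed = NULL, strict = TRUE, keepReplicates = FALSE,
                        perGroup = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logLines <- c(
    sprintf("taxmature %s", as.character(packageVersion("taxmature"))),
    sprintf("tree: %s", treeFile), sprintf("taxonomy: %s", taxonomyFile),
    sprintf("step=%d window=%d nullReps=%d slopeSpan=%d seed=%s",
            step, window, nullReps, slopeSpan,
            if (is.null(seed)) "none" else as.character(seed)))

  cg <- readChronogram(treeFile, strict = strict)
  tab <- if (is.null(traitColumn)) readTaxonomy(taxonomyFile) else
    readTaxonomy(taxonomyFile, traitCol = traitColumn)
  al <- withCallingHandlers(
    alignTreeTaxonomy(cg, tab),
    warning = function(w) {
      logLines <<- c(logLines, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  logLines <- c(logLines,
    sprintf("aligned: %d species; dropped %d tip(s), %d record(s)",
            nSpecies(al$tree), length(al$report@droppedTips),
            length(al$report@droppedRecords)))

  seeds <- .spawnSeeds(seed, 2L)
  schedule <- sliceSchedule(al$table, step = step, window = window)
  traj <- metricTrajectory(al$tree, al$table, schedule,
                           nullReps = nullReps, seed = seeds[1L])
  trajPath <- file.path(outDir, "trajectory.tsv")
  writeTrajectory(traj, trajPath)
  slope <- recentSlope(traj, span = slopeSpan)
  logLines <- c(logLines,
    sprintf("slices: %d (%d-%d)", length(scheduleYears(schedule)),
            schedule@startYear, schedule@finalYear),
    sprintf("recent gamma_OE slope (%d yr): %s", slopeSpan,
            if (is.na(slope)) "undefined" else sprintf("%.6g", slope)))
  paths <- c(trajectory = trajPath)
  out <- list(trajectory = traj, recentSlope = slope, schedule = schedule,
              alignment = al$report)

  traits <- traitValues(al$table)
  if (!is.null(traits) && sum(is.finite(traits)) >= 3L) {
    ts <- traitSeries(al$tree, al$table, schedule = schedule)
    tsPath <- file.path(outDir, "trait_series.tsv")
    writeTrajectory(ts, tsPath)
    paths <- c(paths, traits = tsPath)
    out$traitSeries <- ts
    logLines <- c(logLines, sprintf("trait series: %d row(s)",
                                    nrow(as.data.frame(ts))))
  }

  if (!is.null(forecastAtYear)) {
    past <- pruneToYear(al$tree, al$table, forecastAtYear)
    nAdd <- nSpecies(al$tree) - nSpecies(past)
    fc <- forecastGamma(past, nAdd = nAdd, reps = forecastReps,
                        seed = seeds[2L], sourceYear = forecastAtYear)
    fcPath <- file.path(outDir, "forecast.tsv")
    .writeTsv(data.frame(source_year = forecastAtYear, n_add = nAdd,
                         gamma_mean = mean(fc@replicates),
                         gamma_p2_5 = fc@lower, gamma_p97_5 = fc@upper,
                         gamma_present = gammaStatistic(al$tree)), fcPath)
    paths <- c(paths, forecast = fcPath)
    if (keepReplicates) {
      repPath <- file.path(outDir, "forecast_replicates.tsv")
      .writeTsv(data.frame(source_year = forecastAtYear, n_add = nAdd,
                           rep = seq_along(fc@replicates),
                           gamma = fc@replicates), repPath)
      paths <- c(paths, forecastReplicates = repPath)
    }
    out$forecast <- fc
    logLines <- c(logLines,
      sprintf("forecast from %d: n_add=%d gamma in [%.4f, %.4f], present %.4f",
              forecastAtYear, nAdd, fc@lower, fc@upper,
              gammaStatistic(al$tree)))
  }

  df <- as.data.frame(al$table)
  if (perGroup && "group" %in% names(df)) {
    for (g in sort(unique(df$group))) {
      sub <- df[df$group == g, , drop = FALSE]
      if (nrow(sub) < 3L) {
        logLines <- c(logLines,
          sprintf("group '%s': skipped (<3 species)", g))
        next
      }
      alg <- tryCatch(
        suppressWarnings(alignTreeTaxonomy(cg, TaxonomyTable(sub))),
        error = function(e) NULL)
      if (is.null(alg)) {
        logLines <- c(logLines, sprintf("group '%s': skipped (alignment failed)", g))
        next
      }
      schg <- sliceSchedule(alg$table, step = step, window = window)
      trg <- metricTrajectory(alg$tree, alg$table, schg,
                              nullReps = nullReps, seed = seeds[1L])
      gp <- file.path(outDir, sprintf("trajectory_%s.tsv", gsub("\\W+", "_", g)))
      writeTrajectory(trg, gp)
      paths <- c(paths, setNames(gp, paste0("trajectory_", g)))
      logLines <- c(logLines, sprintf("group '%s': %d slices written", g,
                                      nrow(as.data.frame(trg))))
    }
  }

  writeLines(logLines, logPath)
  paths <- c(paths, log = logPath)
  out$paths <- paths
  invisible(out)
}

#' Plot a metric trajectory
#'
#' Convenience base-graphics panels of mean/min-max added branch lengths,
#' gamma with its null band, gamma_OE, and windowed PD against year. The
#' TSV outputs, not these panels, are the package's contract.
#'
#' @param x a [MetricTrajectory-class].
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plotTrajectory <- function(x, ...) {
  df <- as.data.frame(x)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(df$year, df$bl_mean, type = "l", xlab = "year",
                 ylab = "added BL (mean, min-max)", ...)
  ok <- is.finite(df$bl_min)
  graphics::segments(df$year[ok], df$bl_min[ok], df$year[ok], df$bl_max[ok],
                     col = "grey60")
  graphics::plot(df$year, df$gamma, type = "l", xlab = "year",
                 ylab = expression(gamma), ...)
  graphics::lines(df$year, df$gamma_null_p2_5, lty = 2, col = "grey40")
  graphics::lines(df$year, df$gamma_null_p97_5, lty = 2, col = "grey40")
  graphics::plot(df$year, df$gamma_oe, type = "l", xlab = "year",
                 ylab = expression(gamma[OE]), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(df$year, df$pd_window, type = "h", xlab = "year",
                 ylab = "window PD", ...)
  invisible(x)
}
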