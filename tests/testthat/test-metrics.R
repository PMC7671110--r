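test_that("addedBranchLengths reads pendant edges from the pruned tree", {
  cg <- Chronogram(fixtureTree())
  tab <- fixtureTaxonomy()
  # interval (1850, 1900]: only B is new; its pendant edge in T_1900 is 1
  r <- addedBranchLengths(cg, tab, 1850, 1900)
  expect_equal(r$lengths, c(B = 1))
  expect_equal(c(r$mean, r$max, r$min), c(1, 1, 1))
  # empty interval: summaries undefined, not zero
  r0 <- addedBranchLengths(cg, tab, 1801, 1850)
  expect_length(r0$lengths, 0)
  expect_true(all(is.na(c(r0$mean, r0$max, r0$min))))
  # first slice: everything in T_1 is new
  r1 <- addedBranchLengths(cg, tab, -Inf, 1900)
  expect_equal(sort(unname(r1$lengths)), c(1, 1, 2))
  expect_equal(r1$mean, 4 / 3, tolerance = 1e-9)
  expect_error(addedBranchLengths(cg, tab, 1900, 1850), "yearPrev")
})

test_that("added lengths equal attachment ages under a re-pruning oracle", {
  cg <- simulateTree(30, seed = 21)
  tab <- assignYears(cg, discoveryModel("uniform", startYear = 1850L,
                                        endYear = 1979L), seed = 22)
  yr <- descriptionYears(tab)
  r <- addedBranchLengths(cg, tab, 1920, 1960)
  pruned <- asPhylo(pruneToYear(cg, tab, 1960))
  for (sp in names(r$lengths)) {
    # brute force: pendant edge of sp in an independently re-pruned tree
    keep <- names(yr)[yr <= 1960]
    oracle <- ape::drop.tip(asPhylo(cg), setdiff(speciesNames(cg), keep))
    e <- oracle$edge.length[oracle$edge[, 2] == match(sp, oracle$tip.label)]
    expect_equal(unname(r$lengths[sp]), e, tolerance = 1e-9)
  }
})

test_that("rooted PD matches manual sums and picante on random sets", {
  phy <- fixtureTree()
  expect_equal(phylogeneticDiversity(phy, c("B", "C")), 4)
  expect_equal(phylogeneticDiversity(phy, c("A", "B", "C")),
               sum(phy$edge.length))
  expect_equal(phylogeneticDiversity(phy, "C"), 2)
  expect_error(phylogeneticDiversity(phy, character(0)), "empty")
  expect_error(phylogeneticDiversity(phy, c("A", "Z")), "unknown")

  for (seed in c(4, 17)) {
    cg <- simulateTree(25, seed = seed)
    phy <- asPhylo(cg)
    set.seed(seed)
    for (k in c(2, 5, 20)) {
      sp <- sample(phy$tip.label, k)
      comm <- matrix(as.integer(phy$tip.label %in% sp), nrow = 1,
                     dimnames = list("s", phy$tip.label))
      expect_equal(phylogeneticDiversity(cg, sp),
                   picante::pd(comm, phy, include.root = TRUE)$PD,
                   tolerance = 1e-9)
    }
  }
})

test_that("PD is monotone under set inclusion", {
  cg <- simulateTree(40, seed = 31)
  phy <- asPhylo(cg)
  set.seed(32)
  sp <- sample(phy$tip.label)
  pds <- vapply(2:40, function(k) phylogeneticDiversity(cg, sp[1:k]),
                numeric(1))
  expect_true(all(diff(pds) >= -1e-12))
  expect_equal(pds[39], sum(phy$edge.length), tolerance = 1e-9)
})

test_that("BL and PD scale with branch lengths; gamma does not", {
  cg <- simulateTree(20, seed = 41)
  tab <- assignYears(cg, discoveryModel("uniform", startYear = 1900L,
                                        endYear = 1989L), seed = 42)
  phy <- asPhylo(cg)
  scaled <- phy; scaled$edge.length <- scaled$edge.length * 3
  cgs <- Chronogram(scaled)
  r1 <- addedBranchLengths(cg, tab, 1930, 1970)
  r2 <- addedBranchLengths(cgs, tab, 1930, 1970)
  expect_equal(r2$lengths, r1$lengths * 3, tolerance = 1e-9)
  sp <- speciesNames(cg)[1:7]
  expect_equal(phylogeneticDiversity(cgs, sp),
               3 * phylogeneticDiversity(cg, sp), tolerance = 1e-9)
  expect_equal(gammaStatistic(cgs), gammaStatistic(cg), tolerance = 1e-9)
})

test_that("metricTrajectory composes the per-slice metrics", {
  cg <- Chronogram(fixtureTree())
  tab <- fixtureTaxonomy()
  sch <- sliceSchedule(tab, step = 50)
  traj <- metricTrajectory(cg, tab, sch, window = 5, nullReps = 20, seed = 1)
  df <- as.data.frame(traj)
  # schedule starts at the third species' year (1900 = final year): one row
  expect_equal(nrow(df), length(scheduleYears(sch)))
  expect_identical(df$year, 1900L)
  expect_equal(df$n_tips, 3L)
  # first slice: all of T_1 counts as new
  expect_equal(df$n_added_window, 3L)
  expect_equal(df$bl_mean, 4 / 3, tolerance = 1e-9)
  expect_equal(df$pd_window, 5)
  expect_equal(df$gamma, -0.346410, tolerance = 1e-6)
  # no missing species: degenerate null, gamma_oe exactly 0
  expect_identical(df$gamma_oe, 0)
  expect_identical(df$gamma_null_mean, df$gamma)
})

test_that("trajectory rows are internally consistent on simulated data", {
  cg <- simulateTree(60, seed = 51, scaleHeight = TRUE)
  tab <- assignYears(cg, discoveryModel("uniform"), seed = 52)
  sch <- sliceSchedule(tab, step = 20)
  traj <- metricTrajectory(cg, tab, sch, nullReps = 50, seed = 53)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), length(scheduleYears(sch)))
  expect_true(all(diff(df$n_tips) >= 0))
  ok <- is.finite(df$bl_mean)
  expect_true(all(df$bl_min[ok] <= df$bl_mean[ok] + 1e-12))
  expect_true(all(df$bl_mean[ok] <= df$bl_max[ok] + 1e-12))
  expect_true(all(is.finite(df$gamma)))
  expect_true(all(df$gamma_null_p2_5 <= df$gamma_null_p97_5))
  expect_equal(df$gamma_oe, df$gamma - df$gamma_null_mean, tolerance = 1e-12)
  expect_identical(df$gamma_oe[nrow(df)], 0)
  expect_named(df, c("year", "n_tips", "n_added_window", "bl_mean", "bl_max",
                     "bl_min", "gamma", "gamma_null_mean", "gamma_null_p2_5",
                     "gamma_null_p97_5", "gamma_oe", "pd_window"))
})
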