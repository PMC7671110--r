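test_that("simulateTree yields valid, reproducible chronograms", {
  cg <- simulateTree(50, seed = 1)
  expect_equal(nSpecies(cg), 50L)
  expect_true(ape::is.ultrametric(asPhylo(cg), tol = 1e-9))
  cg2 <- simulateTree(50, seed = 1)
  expect_identical(ape::write.tree(asPhylo(cg)), ape::write.tree(asPhylo(cg2)))
  expect_false(identical(ape::write.tree(asPhylo(simulateTree(50, seed = 2))),
                         ape::write.tree(asPhylo(cg))))
  expect_equal(treeHeight(simulateTree(20, seed = 3, scaleHeight = TRUE)), 1,
               tolerance = 1e-9)
  expect_error(simulateTree(2), "nTips")
  expect_error(simulateTree(10, birth = 0.5, death = 0.5), "birth")
  expect_error(simulateTree(10, birth = 1, death = -0.1), "birth")
})

test_that("pure-birth trees have gamma centred near zero", {
  # constant-rates property of the statistic, checked by Monte Carlo
  g <- vapply(1:120, function(s)
    gammaStatistic(simulateTree(60, birth = 1, death = 0, seed = 1000 + s)),
    numeric(1))
  expect_lt(abs(mean(g)), 0.25)
  expect_lt(abs(mean(g)) / (sd(g) / sqrt(length(g))), 4)
})

test_that("assignYears covers every tip and aligns without drops", {
  cg <- simulateTree(40, seed = 5, scaleHeight = TRUE)
  for (m in list(discoveryModel("uniform"),
                 discoveryModel("depth_biased", beta = 3),
                 discoveryModel("depth_biased", beta = 0))) {
    tab <- assignYears(cg, m, seed = 6)
    expect_setequal(speciesNames(tab), speciesNames(cg))
    yr <- descriptionYears(tab)
    expect_true(all(yr >= 1758L & yr <= 2019L))
    al <- alignTreeTaxonomy(cg, tab)
    expect_length(al$report@droppedTips, 0)
    expect_length(al$report@droppedRecords, 0)
  }
  t1 <- assignYears(cg, discoveryModel("uniform"), seed = 7)
  t2 <- assignYears(cg, discoveryModel("uniform"), seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("trait-biased orders need traits and follow them", {
  cg <- simulateTree(60, seed = 8, scaleHeight = TRUE)
  expect_error(assignYears(cg, discoveryModel("trait_biased", beta = 2)),
               "traits")
  x <- simulateTrait(cg, sigma2 = 1, seed = 9)
  tab <- assignYears(cg, discoveryModel("trait_biased", beta = 8),
                     seed = 10, traits = x)
  yr <- descriptionYears(tab)
  early <- names(sort(yr))[1:12]
  late <- names(sort(yr, decreasing = TRUE))[1:12]
  expect_gt(mean(x[early]), mean(x[late]))
})

test_that("depth bias describes deep-attaching species first", {
  hits <- 0L
  for (s in 1:10) {
    cg <- simulateTree(100, seed = 200 + s, scaleHeight = TRUE)
    tab <- assignYears(cg, discoveryModel("depth_biased", beta = 5),
                       seed = 300 + s)
    yr <- descriptionYears(tab)
    ord <- names(sort(yr))
    # attachment age of each species against everything described before it
    v <- ape::vcv(asPhylo(cg))
    h <- max(diag(v))
    att <- function(block, prior)
      vapply(block, function(sp) h - max(v[sp, prior]), numeric(1))
    first <- ord[1:20]; last <- ord[81:100]
    aFirst <- c(h, vapply(2:20, function(i)
      h - max(v[ord[i], ord[1:(i - 1)]]), numeric(1)))
    aLast <- att(last, ord[1:80])
    if (mean(aFirst) > mean(aLast)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("added branch lengths decline over depth-biased histories", {
  hits <- 0L
  for (s in 1:10) {
    cg <- simulateTree(100, seed = 400 + s, scaleHeight = TRUE)
    tab <- assignYears(cg, discoveryModel("depth_biased", beta = 5),
                       seed = 500 + s)
    sch <- sliceSchedule(tab, step = 5)
    yrs <- scheduleYears(sch)
    q <- length(yrs) %/% 4
    blAt <- function(idx) {
      ls <- unlist(lapply(idx, function(i) {
        lo <- if (i == 1) -Inf else yrs[i] - sch@step
        addedBranchLengths(cg, tab, lo, yrs[i])$lengths
      }))
      mean(ls)
    }
    if (blAt(seq_len(q)) > blAt(seq.int(length(yrs) - q + 1, length(yrs))))
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("simulateTrait draws from the exact model covariance", {
  cg <- simulateTree(25, seed = 11)
  x0 <- simulateTrait(cg, sigma2 = 0, root = 3.5, seed = 12)
  expect_true(all(x0 == 3.5))
  expect_named(x0)
  x1 <- simulateTrait(cg, sigma2 = 1, lambda = 0.5, seed = 13)
  x2 <- simulateTrait(cg, sigma2 = 1, lambda = 0.5, seed = 13)
  expect_identical(x1, x2)
  expect_error(simulateTrait(cg, 1, lambda = 1.5), "lambda")
  expect_error(simulateTrait(cg, -1), "sigma2")

  # lambda = 0: trait distances uncorrelated with patristic distances
  co <- vapply(1:40, function(s) {
    x <- simulateTrait(cg, sigma2 = 1, lambda = 0, seed = 600 + s)
    d <- ape::cophenetic.phylo(asPhylo(cg))
    lt <- lower.tri(d)
    cor(d[lt], as.matrix(dist(x))[rownames(d), colnames(d)][lt])
  }, numeric(1))
  expect_lt(abs(mean(co)), 0.05)
})

test_that("year allocation respects range and intensity ramp", {
  flat <- taxmature:::.allocateYears(100, 1900, 1999, ramp = 0)
  expect_length(flat, 100)
  expect_true(all(flat %in% 1900:1999))
  expect_true(!is.unsorted(flat))
  ramped <- taxmature:::.allocateYears(100, 1900, 1999, ramp = 3)
  expect_length(ramped, 100)
  # more descriptions fall late under a positive ramp
  expect_gt(sum(ramped >= 1950), sum(flat >= 1950))
})

test_that("simulateFixture writes a ready-to-run input pair", {
  d <- tempfile("fix")
  paths <- simulateFixture(d, nTips = 20, model = discoveryModel("uniform"),
                           sigma2 = 1, seed = 99)
  cg <- readChronogram(paths["tree"])
  tab <- readTaxonomy(paths["taxonomy"])
  expect_equal(nSpecies(cg), 20L)
  al <- alignTreeTaxonomy(cg, tab)
  expect_length(al$report@droppedTips, 0)
  expect_false(is.null(traitValues(tab)))
})
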