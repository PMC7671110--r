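#' Random-pruning null distribution for gamma
#'
#' Each replicate removes `nMissing` uniformly chosen tips (without
#' replacement) from the full tree and records the gamma statistic of the
#' pruned tree. Replicate gammas are computed from the induced subtree's
#' internal node ages (consecutive-pair MRCA ages in planar tip order),
#' which is exactly the gamma of the explicitly pruned tree. Percentiles
#' use linear interpolation between order statistics.
#'
#' @param tree the full [Chronogram-class] or ultrametric `phylo`.
#' @param nMissing number of tips to remove per replicate
#'   (`0 <= nMissing <= n - 3`).
#' @param reps number of replicates (default 1000).
#' @param seed integer seed or `NULL`.
#' @param context internal: a precomputed `.sliceContext(tree)`.
#' @return a [GammaNull-class].
#' @export
gammaNull <- function(tree, nMissing, reps = 1000L, seed = NULL,
                      context = NULL) {
  phy <- .phy(tree)
  n <- length(phy$tip.label)
  nMissing <- as.integer(nMissing)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")
  if (nMissing < 0L || n - nMissing < 3L)
    stop(sprintf("nMissing = %d leaves fewer than 3 of %d tips", nMissing, n))
  .setSeed(seed)
  if (nMissing == 0L) {
    # degenerate null: every replicate is the full tree
    g <- rep(gammaStatistic(phy), reps)
    return(new("GammaNull", replicates = g, mean = g[1L],
               lower = g[1L], upper = g[1L], nMissing = nMissing,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  } else {
    ctx <- if (is.null(context)) .sliceContext(phy) else context
    k <- n - nMissing
    g <- vapply(seq_len(reps), function(r) {
      .gammaFromAges(.inducedAges(ctx, sample.int(n, k)))
    }, numeric(1))
  }
  new("GammaNull", replicates = g, mean = mean(g),
      lower = .pct(g, 0.025), upper = .pct(g, 0.975),
      nMissing = nMissing,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Observed-minus-expected gamma
#'
#' @param gammaObs observed gamma of the historical tree.
#' @param null the matching [GammaNull-class] (same number of missing
#'   species, pruned from the same full tree).
#' @return `gammaObs - mean(replicates)`.
#' @export
gammaOE <- function(gammaObs, null) {
  if (!is(null, "GammaNull")) stop("'null' must be a GammaNull")
  gammaObs - null@mean
}

#' OLS slope of gamma_OE over the recent past
#'
#' Ordinary least-squares slope of `gamma_oe` against year over the points
#' with `year > lastYear - span` (and `<= lastYear`). A positive slope
#' indicates a recent extended period in which new species attach close to
#' the tips of the tree.
#'
#' @param series a data frame with columns `year` and `gamma_oe`, or a
#'   [MetricTrajectory-class].
#' @param span length of the recent window in years (default 30).
#' @return slope in gamma_OE units per year, or `NA` when fewer than 3
#'   finite points fall in the window.
#' @export
recentSlope <- function(series, span = 30L) {
  df <- as.data.frame(series)
  if (!all(c("year", "gamma_oe") %in% names(df)))
    stop("series needs 'year' and 'gamma_oe' columns")
  df <- df[is.finite(df$gamma_oe) & is.finite(df$year), , drop = FALSE]
  if (nrow(df) == 0L) return(NA_real_)
  last <- max(df$year)
  df <- df[df$year > last - span, , drop = FALSE]
  if (nrow(df) < 3L) return(NA_real_)
  unname(coef(lm(gamma_oe ~ year, data = df))[2L])
}

# --- random tip grafting ----------------------------------------------------

# edge-interval representation of an ultrametric tree: per edge, the parent
# and child node ids and the ages of its rootward (top) and tipward
# (bottom) ends. Grafting splits an edge at a uniformly drawn age and hangs
# a new pendant edge down to the present, so the tree stays a chronogram
# and existing node ages are untouched.
.edgeIntervals <- function(phy) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  age <- h - depth
  list(parent = phy$edge[, 1L], child = phy$edge[, 2L],
       top = age[phy$edge[, 1L]], bottom = pmax(age[phy$edge[, 2L]], 0),
       n = n, nextId = n + phy$Nnode, height = h,
       isTip = c(rep(TRUE, n), rep(FALSE, phy$Nnode)))
}

# sequential grafting: each added tip picks an edge with probability
# proportional to its length and a uniform position along it, so later
# tips may attach to edges created by earlier ones
.graftEngine <- function(st, nAdd) {
  newAges <- numeric(nAdd)
  for (j in seq_len(nAdd)) {
    len <- st$top - st$bottom
    e <- sample.int(length(len), 1L, prob = len)
    u <- runif(1L, st$bottom[e], st$top[e])
    mid <- st$nextId + 1L
    tip <- st$nextId + 2L
    st$nextId <- tip
    oldChild <- st$child[e]
    oldBottom <- st$bottom[e]
    st$child[e] <- mid
    st$bottom[e] <- u
    st$parent <- c(st$parent, mid, mid)
    st$child <- c(st$child, oldChild, tip)
    st$top <- c(st$top, u, u)
    st$bottom <- c(st$bottom, oldBottom, 0)
    st$isTip <- c(st$isTip, FALSE, TRUE)
    newAges[j] <- u
  }
  st$newAges <- newAges
  st
}

# rebuild a phylo from the interval representation (ape numbering: tips
# 1..ntip, root ntip+1, internals in preorder)
.intervalsToPhylo <- function(st, tipLabels) {
  isTip <- st$isTip[seq_len(st$nextId)]
  ntip <- sum(isTip)
  nint <- st$nextId - ntip
  map <- integer(st$nextId)
  map[which(isTip)] <- seq_len(ntip)
  children <- split(seq_along(st$parent), st$parent)
  root <- setdiff(unique(st$parent), st$child)
  stopifnot(length(root) == 1L)
  nextInt <- ntip
  edgeP <- integer(length(st$parent)); edgeC <- integer(length(st$parent))
  edgeL <- numeric(length(st$parent)); k <- 0L
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nextInt <- nextInt + 1L
    map[node] <- nextInt
    for (e in children[[as.character(node)]]) {
      k <- k + 1L
      edgeP[k] <- node; edgeC[k] <- st$child[e]; edgeL[k] <- st$top[e] - st$bottom[e]
      if (!st$isTip[st$child[e]]) stack <- c(stack, st$child[e])
    }
  }
  phy <- list(edge = cbind(map[edgeP], map[edgeC]),
              edge.length = edgeL, tip.label = tipLabels,
              Nnode = nint)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Graft random tips onto an ultrametric tree
#'
#' Adds `nAdd` tips sequentially: each attachment point is drawn uniformly
#' over the total branch length of the current tree (edge chosen with
#' probability proportional to its length, position uniform along it) and
#' the new pendant edge extends to the present, so the augmented tree is
#' ultrametric with unchanged height and untouched existing node ages.
#'
#' @param tree a [Chronogram-class] or ultrametric `phylo`.
#' @param nAdd number of tips to add (>= 0).
#' @param seed integer seed or `NULL`.
#' @param labels labels for the new tips (default `added_1 ...`).
#' @return the augmented tree as a `phylo`.
#' @export
graftRandomTips <- function(tree, nAdd, seed = NULL, labels = NULL) {
  phy <- .phy(tree)
  nAdd <- as.integer(nAdd)
  if (nAdd < 0L) stop("nAdd must be >= 0")
  if (nAdd == 0L) return(phy)
  .setSeed(seed)
  if (is.null(labels)) labels <- paste0("added_", seq_len(nAdd))
  st <- .graftEngine(.edgeIntervals(phy), nAdd)
  .intervalsToPhylo(st, c(phy$tip.label, labels))
}

#' Forecast present-day gamma by random tip addition
#'
#' Per replicate, `nAdd` tips are grafted onto the past knowledge tree as
#' in [graftRandomTips()] and gamma recorded on the augmented tree; the
#' replicate distribution expresses the range of present-day gamma values
#' compatible with adding the missing species at random positions.
#'
#' @param pastTree the historical [Chronogram-class] (or ultrametric
#'   `phylo`) to augment.
#' @param nAdd number of missing species to add per replicate.
#' @param reps number of replicates (default 100).
#' @param seed integer seed or `NULL`.
#' @param sourceYear knowledge year the source tree represents (recorded
#'   in the result; optional).
#' @param keepTrees also return the augmented `phylo` trees (default
#'   `FALSE`).
#' @return a [GammaForecast-class].
#' @export
forecastGamma <- function(pastTree, nAdd, reps = 100L, seed = NULL,
                          sourceYear = NA, keepTrees = FALSE) {
  phy <- .phy(pastTree)
  nAdd <- as.integer(nAdd)
  reps <- as.integer(reps)
  if (nAdd < 0L) stop("nAdd must be >= 0")
  if (reps < 1L) stop("reps must be >= 1")
  n <- length(phy$tip.label)
  if (n < 3L) stop("past tree needs at least 3 tips")
  .setSeed(seed)
  baseAges <- .internalAgesMult(phy)
  base <- .edgeIntervals(phy)
  g <- numeric(reps)
  trees <- if (keepTrees) vector("list", reps) else list()
  labels <- if (nAdd > 0L) paste0("added_", seq_len(nAdd)) else character(0)
  for (r in seq_len(reps)) {
    if (nAdd == 0L) {
      g[r] <- .gammaFromAges(baseAges)
      if (keepTrees) trees[[r]] <- phy
    } else {
      st <- .graftEngine(base, nAdd)
      g[r] <- .gammaFromAges(c(baseAges, st$newAges))
      if (keepTrees)
        trees[[r]] <- .intervalsToPhylo(st, c(phy$tip.label, labels))
    }
  }
  new("GammaForecast", replicates = g, nAdd = nAdd,
      sourceYear = if (is.na(sourceYear)) NA_integer_ else as.integer(sourceYear),
      lower = .pct(g, 0.025), upper = .pct(g, 0.975),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      trees = trees)
}
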