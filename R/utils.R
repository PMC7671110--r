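# internal helpers shared across modules

.tipDepths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  d[seq_len(length(phy$tip.label))]
}

.phy <- function(x) {
  if (is(x, "Chronogram")) return(x@tree)
  if (inherits(x, "phylo")) return(x)
  stop("expected a Chronogram or 'phylo' object")
}

.chronogram <- function(x, tolerance = 1e-6) {
  if (is(x, "Chronogram")) x else Chronogram(x, tolerance = tolerance)
}

# ages of internal nodes repeated (n_children - 1) times, so that a node
# resolving a k-furcation contributes k-1 lineage increments; for a fully
# bifurcating tree this is just the n-1 branching times
.internalAgesMult <- function(phy, warn.polytomy = FALSE) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  nchild <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  internal <- (n + 1L):(n + phy$Nnode)
  mult <- nchild[internal] - 1L
  if (warn.polytomy && any(mult > 1L))
    warning("polytomies present: treated as zero-duration internode intervals")
  rep(h - depth[internal], mult)
}

# gamma from the multiset of internal node ages of an ultrametric tree
# (root age = tree height); length(ages) must be n - 1
.gammaFromAges <- function(ages) {
  m <- length(ages)
  n <- m + 1L
  if (n < 3L) stop("gamma is undefined for fewer than 3 tips")
  a <- sort(ages, decreasing = TRUE)
  g <- c(a[-m] - a[-1L], a[m])        # internode durations g_2 ... g_n
  j <- 2:n
  jg <- j * g
  Tstar <- sum(jg)
  if (Tstar <= 0) stop("total lineage-time is zero")
  inner <- sum(cumsum(jg)[seq_len(n - 2L)])
  (inner / (n - 2L) - Tstar / 2) / (Tstar * sqrt(1 / (12 * (n - 2L))))
}

# precomputed context for fast gamma on induced (pruned) subtrees:
# pairwise MRCA ages plus the left-to-right tip order of a planar drawing
.sliceContext <- function(phy) {
  n <- length(phy$tip.label)
  v <- ape::vcv(phy)                  # depth of the MRCA of each tip pair
  h <- max(diag(v))
  cl <- ape::reorder.phylo(phy, "cladewise")
  kids <- cl$edge[, 2]
  tipOrder <- kids[kids <= n]
  rank <- integer(n)
  rank[tipOrder] <- seq_len(n)
  list(mrcaAge = h - v, rank = rank, n = n, height = h)
}

# internal node ages of the subtree induced by tip indices `keep`:
# MRCA ages of consecutive kept tips in planar order enumerate the induced
# internal nodes with multiplicity (children - 1)
.inducedAges <- function(ctx, keep) {
  o <- keep[order(ctx$rank[keep])]
  k <- length(o)
  ctx$mrcaAge[cbind(o[-k], o[-1L])]
}

# derive per-component integer seeds from one root seed
.spawnSeeds <- function(seed, k) {
  if (is.null(seed) || is.na(seed)) return(rep(NA_integer_, k))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

.setSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
}

.pct <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE))
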