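# shared fixtures and independent oracles

fixtureTree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

fixtureTaxonomy <- function()
  TaxonomyTable(data.frame(species = c("A", "B", "C"),
                           year = c(1758L, 1900L, 1800L)))

writeFixtureFiles <- function(dir = tempfile("fix")) {
  dir.create(dir)
  tf <- file.path(dir, "tree.nwk")
  xf <- file.path(dir, "taxonomy.tsv")
  writeLines("((A:1,B:1):1,C:2);", tf)
  writeLines(c("species\tyear", "A\t1758", "B\t1900", "C\t1800"), xf)
  list(tree = tf, taxonomy = xf, dir = dir)
}

# naive loop evaluation of the constant-rates gamma formula, written
# directly from the closed-form sums; independent of the package's
# internode bookkeeping
naiveGamma <- function(phy) {
  n <- length(phy$tip.label)
  a <- c(sort(unname(ape::branching.times(phy)), decreasing = TRUE), 0)
  g <- numeric(n)
  for (j in 2:n) g[j] <- a[j - 1] - a[j]
  Tstar <- 0
  for (j in 2:n) Tstar <- Tstar + j * g[j]
  ssum <- 0
  for (i in 2:(n - 1)) for (k in 2:i) ssum <- ssum + k * g[k]
  (ssum / (n - 2) - Tstar / 2) / (Tstar * sqrt(1 / (12 * (n - 2))))
}

# GLS machinery on the full Brownian covariance: minimized quadratic form
# and log-likelihood at a given lambda (matrix route, no pruning algorithm)
glsBrownian <- function(phy, x, lambda = 1) {
  x <- x[phy$tip.label]
  C <- ape::vcv(phy)
  V <- C * lambda
  diag(V) <- diag(C)
  Vi <- solve(V)
  one <- rep(1, length(x))
  a <- as.numeric((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  r <- x - a
  q <- as.numeric(t(r) %*% Vi %*% r)
  n <- length(x)
  s2 <- q / n
  list(a = a, q = q, sigma2ML = s2,
       loglik = -0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus[1] + n))
}
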