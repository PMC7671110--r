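---
title: "Quantifying taxonomic maturation on dated phylogenies"
author: "taxmature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying taxonomic maturation on dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Our inventory of species is incomplete, and the species still missing from
a phylogeny are rarely missing at random. `taxmature` asks a historical
version of this question: given a dated, ultrametric species-level
phylogeny (a chronogram) and the year each species was scientifically
described, what did phylogenetic knowledge look like at every point in the
past ~250 years of taxonomy, and how did each wave of newly described
species reshape the tree? Clades differ strikingly in this respect: in
some, early naturalists rapidly sketched out the deep lineages and modern
work only fills in tips (a "mature" taxonomy); in others, long branches
are still being added today, and analyses that assume near-complete
sampling are fragile.

# The procedure

The two inputs are a rooted ultrametric chronogram `T` with unique tip
labels and a table mapping each tip to an integer description year
(optionally with a grouping column and a continuous trait). After
alignment (tips without years are pruned; records not in the tree are
dropped; the intersection must hold at least 3 species), the historical
tree `T_n` at year `n` is `T` pruned to the species described in or before
`n`, with traversed edges merged so every retained root-to-tip distance is
preserved. The evaluation schedule starts at the year the third species
was described (the first slice may hold more than three species when years
tie) and advances in steps of `step` years, always ending exactly at the
final description year.

Per evaluation year the package records:

* **Added branch lengths (BL).** For each species described in the
  trailing `window` years, its pendant edge length in `T_n` — for an
  ultrametric tree, the age at which its lineage diverges from the closest
  previously known species. The window pools the individual lengths and
  summarises the pool (mean/max/min); pooling weights species, not years,
  which is the less distortion-prone reading of a windowed average.
  Windows that add no species yield missing values, never zeros — a zero
  would fake a signal of tip-adjacent additions.
* **Gamma.** The constant-rates statistic of the lineage-through-time
  sequence: with internode durations `g_j` while `j` lineages exist and
  `T* = sum_{j=2}^{n} j g_j`,
  `gamma = [ (1/(n-2)) sum_{i=2}^{n-1} sum_{k=2}^{i} k g_k - T*/2 ] /
  [ T* sqrt(1/(12(n-2))) ]`.
  Negative values mean nodes concentrated toward the root. Because gamma
  drifts as tips are added, each slice is compared against a null: remove
  the same number of tips from the *complete* tree uniformly at random
  (1000 replicates by default), record gamma of each pruned replicate, and
  report the mean and the 2.5/97.5 percentiles (linear interpolation
  between order statistics, so results are bit-reproducible). The
  observed-minus-expected gamma, `gamma_OE = gamma_obs - mean(null)`,
  makes slices comparable across tree sizes; the mean (not the median) is
  the expectation because it is the conventional estimator and stable at
  1000 replicates. The OLS slope of `gamma_OE` over the trailing 30 years
  summarises the recent regime: positive slopes mean recent additions sit
  near the tips.
* **Phylogenetic diversity (PD).** The summed branch lengths of the
  subtree spanning the window's newly described species, measured on the
  full tree and *rooted*: the path to the root is included, which is what
  pruning the full tree down to the set and summing the remaining branches
  yields, and it keeps singleton sets well defined.

Null percentiles are reported per slice without multiple-testing
adjustment across years; consecutive slices are strongly dependent
(nested trees), so a familywise correction would be both awkward and
misleading. This is documented rather than "fixed".

**Forecasting.** To ask whether the present-day gamma was predictable from
a past knowledge state, the missing species are grafted back at random:
each new tip picks an attachment point uniformly over the total branch
length of the current tree (edge with probability proportional to length,
position uniform along it) and its pendant edge extends to the present, so
the augmented tree remains a chronogram with untouched existing node ages.
Grafting is sequential within a replicate — later tips may attach to
edges created by earlier ones — matching the incremental semantics of the
standard random-addition routines. One hundred replicates give a gamma
distribution for "what the tree might look like".

**Trait dynamics.** For a continuous trait (used as given; log-transform
body sizes first), each slice yields the Brownian rate as the mean squared
standardized independent contrast and the maximum-likelihood Pagel's
lambda. Lambda multiplies the off-diagonal (shared-path) entries of the
Brownian covariance, leaving tip variances exact — a covariance-level
transform rather than branch-length manipulation, which stays correct for
marginally non-ultrametric inputs. The root state and rate are profiled
out by GLS; lambda is maximized on [0, 1] by bounded scalar search
(tolerance 1e-6) with explicit endpoint checks, since 0 and 1 are common
maximizers. On a star tree the likelihood is flat in lambda and the fit is
flagged non-identifiable instead of returning an arbitrary number.
Polytomies are an error for contrasts (resolution is the caller's choice);
for gamma they are treated as simultaneous divergences contributing
zero-duration internodes, with a warning.

# The synthetic-data generator

Everything is testable without external data. The generator emulates the
shape of the empirical inputs the method targets:

* `simulateTree(n, birth, death)` — constant-rate birth–death chronograms
  conditioned on the number of extant tips; study conditions in the tests
  use `birth = 1, death = 0` and height normalised to 1, so that bias
  strengths act on relative node ages and are comparable across trees.
* `assignYears(tree, discoveryModel(...))` — description histories over
  1758–2019 (constant per-year intensity by default, linear ramp
  optional). `uniform` draws a uniform permutation. `depth_biased` picks
  species sequentially with weight `exp(beta * a_s)`, where the attachment
  age `a_s` is recomputed against the already-described set at each draw —
  deliberately the same quantity the BL metric measures, so generator and
  metric live on one scale. `trait_biased` weights by the standardized
  trait. `beta = 0` collapses every model to uniform.
* `simulateTrait(tree, sigma2, lambda)` — one exact multivariate-normal
  draw from `sigma2 * C(lambda)` (matrix square root, not recursive
  simulation), so `lambda != 1` traits follow the model exactly.

What passing tests show — and what they do not: simulated histories have
no synonymy, no geographic structure, no description-intensity bursts, no
cryptic-species waves, and uniform histories make the described set at
each year an exchangeable random subset (the best case for the null). Real
catalogs violate all of these; the tests establish that the machinery is
correct and that the maturation signature is recoverable when present, not
that any particular empirical clade will show it.

With depth-biased discovery (`beta = 5`, 200 tips) the simulated
trajectories reproduce the canonical maturation arc: gamma drops below the
null 2.5% percentile in the middle third of the history, and the 30-year
`gamma_OE` slope is positive in the final third as late descriptions crowd
the tips; under uniform discovery the observed gamma stays inside the
band at roughly the nominal rate. The added-BL pool declines from the
first to the last quarter of biased histories. These checks run at a
scaled-down size — 200-replicate nulls rather than 1000, 5-year steps,
50 seeds per condition — chosen as the smallest design whose pass/fail
thresholds are stable across reruns.

# A known limitation of random-addition forecasts

The forecast calibration experiment (prune a uniform-history tree to half
its tips, graft the missing half back at random, ask whether the replicate
2.5–97.5% gamma interval brackets the truth) fails far more often than
not under these study conditions, and the failure is a property of the
method, not of the implementation: the package's kernel was cross-checked
against an independent random-addition routine and produces the same
distribution. Random deletion from a constant-rate tree removes
predominantly very young internal nodes, whereas length-uniform
attachment inserts nodes following the lineage-through-time profile,
which is older on average; augmented trees therefore stay about as
stem-heavy as the pruned tree and their gamma interval sits below the
true value. Forecasts of this kind are best read as "what if the missing
species were phylogenetically random", a scenario analysis rather than a
calibrated predictor — consistent with the observation that such
predictions do not invariably encompass the present-day value.

# Numerical and interface choices

* Ultrametricity is validated to a relative tolerance of `1e-6` times the
  tree height; lenient mode warns and records the deviation but never
  rescales — silent repair would corrupt node ages.
* Description years before 1758 are accepted with a warning (botanical
  names begin in 1753; the framework is calendar-agnostic).
* When pruning leaves the original root with one surviving child lineage,
  the basal unifurcation is suppressed (new root at the first surviving
  bifurcation), the standard drop-tip semantics on which gamma and PD are
  defined downstream.
* Null replicate gammas are computed from the induced subtree's internal
  node ages (consecutive-pair MRCA ages in planar tip order) — an exact
  identity with explicit pruning, verified bit-for-bit in the tests, and
  the reason thousands of per-slice replicates are affordable.
* Every stochastic function takes an integer `seed`; the pipeline derives
  all component seeds from one root seed (trajectory nulls first, then
  the forecast), so a rerun with the same inputs and seed is
  byte-identical.
* Defaults follow the analysis settings the method was designed around:
  1000-replicate nulls, 100-replicate forecasts, 5-year window, 30-year
  slope span, 1-year step.

# Limitations

Beyond the forecast caveat above: the framework takes the current tree as
the best estimate of the true tree and does not model how adding taxa
changes inferred *topology*; reticulate evolution is out of scope;
sub-annual dating and synonym reconciliation between tree and catalog are
not attempted (labels must match exactly); and chronogram estimation —
converting non-ultrametric trees to time trees — must happen upstream.
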