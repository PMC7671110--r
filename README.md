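# taxmature

**Taxonomic maturation analysis of time-calibrated phylogenies.**

Species are still being described, and the ones still missing from a
phylogeny are rarely missing at random. `taxmature` is for systematists
and comparative biologists who want to know *how known* a clade's
phylogeny actually is before building analyses on it. From two inputs — a
rooted ultrametric chronogram (Newick) and a table of species description
years (TSV/CSV) — it reconstructs the phylogeny as it was known in every
year of taxonomic history and quantifies how each wave of newly described
species changed it.

## What it computes

For the historical tree *T<sub>n</sub>* (the full tree *T* pruned to
species described by year *n*), per evaluation year:

* **BL** — pendant branch lengths added by the window's new species in
  *T<sub>n</sub>*: how phylogenetically distinct each new species was from
  everything already known. Well-known clades show declining mean and
  range of BL.
* **γ** — the constant-rates tree-shape statistic computed from internode
  durations *g<sub>j</sub>* of the lineage-through-time sequence, with
  *T\** = Σ<sub>j=2..n</sub> *j g<sub>j</sub>*:

  γ = [ (1/(n−2)) Σ<sub>i=2..n−1</sub> Σ<sub>k=2..i</sub> *k g<sub>k</sub>* − *T\**/2 ] / [ *T\** √(1/(12(n−2))) ]

* **γ null band and γ_OE** — γ of *T* with the same number of tips removed
  uniformly at random (1000 replicates; 2.5/97.5 percentiles), and
  γ_OE = γ<sub>obs</sub> − mean(null). Periods when taxonomists described
  unexpectedly divergent lineages show γ below the band; a positive
  30-year slope of γ_OE means recent species attach near the tips.
* **PD** — rooted phylogenetic diversity (Faith) of the window's new
  species on the full tree: whether a year's descriptions were spread
  across the tree or packed into one subclade.
* **Forecasts** — distribution of present-day γ obtained by randomly
  grafting the missing species onto a past knowledge tree (length-uniform
  attachment, pendant extended to the present).
* **Trait dynamics** — mean-squared independent-contrast rate and Pagel's
  λ (ML on [0,1], GLS-profiled) of a continuous trait at every slice.

A full synthetic-data module (`simulateTree`, `assignYears` with uniform /
depth-biased / trait-biased discovery models, `simulateTrait`) generates
realistic inputs so the entire pipeline is testable without external data.

## Worked example

```r
library(taxmature)

## a synthetic clade: 120 species, unit-height pure-birth chronogram,
## deep-lineage-biased discovery over 1758-2019
dir <- tempfile()
simulateFixture(dir, nTips = 120, model = discoveryModel("depth_biased",
                beta = 5), sigma2 = 1, seed = 42)

res <- runPipeline(file.path(dir, "tree.nwk"), file.path(dir, "taxonomy.tsv"),
                   file.path(dir, "out"), step = 5, window = 5,
                   nullReps = 1000, seed = 1)

df <- as.data.frame(res$trajectory)
tail(df[, c("year", "n_tips", "bl_mean", "gamma", "gamma_null_p2_5",
            "gamma_oe", "pd_window")], 3)
res$recentSlope
```

```
   year n_tips    bl_mean     gamma gamma_null_p2_5   gamma_oe pd_window
50 2008    115 0.05212846 0.2422707       0.1328712 -0.2359548  2.000000
51 2013    117 0.04453320 0.4207528       0.2728506 -0.1131589  2.000000
52 2018    120 0.05239267 0.6303141       0.6303141  0.0000000  2.243513
[1] 0.01306841
```

Reading the output: by the 2000s the added branch lengths (`bl_mean`,
~0.05 on a height-1 tree) are tiny — new species attach next to known
ones — and γ_OE climbs back toward 0 with a positive 30-year slope
(`+0.013` per year): the clade's taxonomy has "matured". Mid-history rows
of the same table show γ below `gamma_null_p2_5` (here 29 slices spanning
1773–1973) — the long era when the biased discovery process was finding
deep lineages faster than chance. The final row is the complete tree: no
species are missing, the null is degenerate, and `gamma_oe` is exactly 0.
Windows that add no species report `NA`, not 0.

A command-line wrapper with `run`, `forecast`, `traits` and `simulate`
subcommands is installed at
`system.file("scripts", "taxmature-cli.R", package = "taxmature")`.

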