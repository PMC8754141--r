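# seacomm

Biogeography and assembly processes of marine microbial communities from
OTU count data.

Amplicon surveys of ocean microbiota produce three things: an OTU count
table (samples × OTUs), a phylogeny of the OTUs, and station metadata
(coordinates, region, environmental variables).  `seacomm` takes it from
there, for microbial ecologists asking the two classic biogeography
questions — *do communities differ in space?* and *which ecological
processes make them differ?*  It covers:

* **Alpha diversity** after rarefaction: richness, Shannon (`H = −Σ pᵢ
  log₂ pᵢ`), Faith's PD (total branch length spanning the present taxa),
  and the nearest taxon index `NTI = −(MNTD_obs − x̄_null)/s_null`
  against tip-shuffle nulls.
* **Beta structure**: Bray-Curtis dissimilarity `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`,
  PCoA, ANOSIM, Mantel tests, symmetric Procrustes with Monte-Carlo
  significance (PROTEST), rank-sum group comparisons, and Spearman
  correlation matrices with Benjamini-Hochberg FDR control.
* **Distance decay**: great-circle distances and the regression of
  community similarity on distance, with permutation significance and a
  permutation test for slope differences between groups.
* **Assembly processes** via the two-step phylogenetic null-model
  framework: βNTI = (βMNTD_obs − x̄_null)/s_null classifies pairs with
  |βNTI| > 2 as heterogeneous (+) or homogeneous (−) selection; the
  remaining pairs go to the Bray-Curtis Raup-Crick null, RC_bray =
  2·(P(null < obs) + ½P(null = obs)) − 1, with RC > 0.95 read as
  dispersal limitation, RC < −0.95 as homogenizing dispersal, and the
  rest as ecological drift.  Per-group process fractions summarize the
  result.
* A **synthetic community generator** (Yule phylogenies, Brownian or
  labile niche optima, two-region seascapes, lognormal metacommunities,
  niche filtering, distance-kernel dispersal, multinomial drift) with
  presets for each assembly regime, so the whole pipeline is testable
  against known ground truth.

The inner βMNTD/MNTD null loops are in C++ (Rcpp); everything is
deterministic under a master seed.

## Worked example

Simulate a drift-regime dataset, run the full pipeline and print the
report:

```r
library(seacomm)

cfg <- pipeline_config(
  preset = "drift", seed = 7, n_taxa = 120L,
  n_sites_per_region = c(6L, 6L), depth = 1000L,
  n_rand = list(nti = 199L, bnti = 199L, rc = 199L, anosim = 999L,
                mantel = 999L, protest = 199L, diffslope = 999L),
  out_dir = "drift_run")
bundle <- run_pipeline(cfg)
report(bundle)
```

```
seacomm 0.1.0 | seed 7
samples: 12  OTUs: 120  rarefaction depth: 1000
alpha richness: 114-119 (mean 116.9)
ANOSIM R = -0.194, p = 0.964
distance-decay slope (all) = 6.83e-07 per km, p = 0.654
modal assembly process: drift (95.5% of pairs)
```

Read: the twelve stations do not cluster by region (ANOSIM R near 0,
p ≫ 0.05), community similarity shows no trend with distance, and 95%
of pairwise turnover is attributed to ecological drift — exactly what a
neutral, well-mixed simulation should produce.  `drift_run/` now holds
the tab-delimited results bundle (alpha table, Bray-Curtis and βNTI/RC
matrices, pairwise classifications, per-group process fractions, and a
provenance block).

On a selection-structured dataset the same pipeline reports the
opposite: `scenario_preset("heterogeneous_selection", ...)` gives
region-separated PCoA clusters, a significant ANOSIM, and heterogeneous
selection as the modal process among cross-region pairs.

A thin command-line wrapper ships in `inst/cli/seacomm.R`:

```sh
Rscript inst/cli/seacomm.R run --preset drift --seed 7 --out drift_run
```

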