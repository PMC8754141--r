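---
title: "Diversity, distance decay, and community assembly with seacomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, distance decay, and community assembly with seacomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seacomm)
```

## What the package computes

`seacomm` analyses microbial OTU count tables from spatial surveys — the
kind produced by 16S/18S amplicon sequencing of, say, surface-ocean
stations spanning two oceanographic regions.  Its stages are:

1. **Alpha diversity** after rarefaction to a common depth: observed
   richness, Shannon diversity (bits by default), Faith's phylogenetic
   diversity, and the nearest taxon index (NTI).
2. **Beta structure**: Bray-Curtis dissimilarity, principal coordinates,
   ANOSIM, Mantel tests, Procrustes/PROTEST, rank-sum group comparisons,
   Spearman + FDR correlation matrices, and PCA of standardized
   environmental variables.
3. **Distance decay**: great-circle distances, similarity-on-distance
   regression with Mantel-style permutation significance, and a
   permutation test for differences between decay slopes.
4. **Assembly processes**: the two-step phylogenetic null-model
   framework.  The beta nearest taxon index (βNTI) z-scores the observed
   between-community mean nearest taxon distance (βMNTD) against
   tip-shuffle nulls; pairs with |βNTI| > 2 are attributed to selection
   (heterogeneous when positive, homogeneous when negative).  For the
   remaining pairs, the Bray-Curtis Raup-Crick metric (RC_bray) locates
   the observed compositional turnover in a probabilistic assembly null;
   RC > 0.95 indicates dispersal limitation, RC < −0.95 homogenizing
   dispersal, and the rest is ascribed to ecological drift.

A synthetic-community generator produces datasets under known assembly
regimes so every stage can be validated against ground truth without any
sequencing data.

## The null models and their conventions

**NTI.**  For each sample, the mean nearest taxon distance over present
taxa is compared with nulls built by shuffling tip labels across the
full taxon pool; one shuffle per randomization is shared by all samples.
`NTI = −(MNTD_obs − mean_null) / sd_null`, so phylogenetically clustered
samples score positive.  NTI is presence-based by default (the
convention of the reference implementation in picante); βMNTD/βNTI are
abundance-weighted by default (the convention of the assembly
framework).  Both are flags.

**βNTI.**  Each of the 999 default randomizations shuffles tip
identities on the cophenetic matrix once and recomputes βMNTD for every
pair.  One shared shuffle per randomization is statistically equivalent
to per-pair shuffles and roughly n² cheaper.  A subtle degenerate case
matters: when two samples have identical taxon support, βMNTD is zero
under *every* shuffle — the null is a point mass the observation hits
exactly.  There is no selection signal in that situation (the z-score's
limit is 0), so such pairs are assigned βNTI = 0 and fall through to the
RC step, which is the step able to say something about two
membership-identical communities.  A point-mass null the observation
*misses* is genuinely undefined and reported as `NA`.

**RC_bray.**  Null communities preserve each sample's richness and
total: species are drawn without replacement proportionally to occupancy
across the analysis group, seeded with one individual, and remaining
individuals are placed with replacement proportionally to summed
relative abundance among the drawn species.  Bray-Curtis values are
rounded to 1e-9 before tie counting because integer counts give rational
values that can differ by float noise.  Occupancy and abundance weights
default to the table being analysed but can be supplied explicitly, so
the weights may come from a wider analysis group than the pair set — and
so the null can be tested against data generated by itself.

**Permutation tests.**  ANOSIM, Mantel and PROTEST are one-sided with
`p = (exceedances + 1) / (n_perm + 1)`; the decay fit and the
slope-difference test are two-sided on the slope.  ANOSIM and Mantel
additionally offer exhaustive enumeration of all distinct label
arrangements (used by the test suite to compare against brute-force
oracles).  Ties always receive average ranks.  The group-comparison test
is the unpaired rank-sum (Mann-Whitney) test; a `paired` flag switches
to the signed-rank variant.

## The synthetic generator

The generator emulates a two-region tropical-ocean survey: by default 13
and 16 stations in two longitude bands (reflecting a western/central
basin design), one or more environmental variables that are linear in
longitude plus a region offset and station noise, a pure-birth phylogeny
of 300 OTUs, and niche optima evolved along it by Brownian motion.

Counts arise from a hierarchical model:

* each region has a lognormal (sd_log = 1) metacommunity abundance
  vector over its species pool; a fraction φ of taxa is shared between
  regions (shared taxa receive the average of the two regions' draws, so
  φ = 1 means identical pools);
* a site's expected relative abundances weight the regional pool by a
  Gaussian niche kernel `exp(−(env − optimum)² / 2σ²)`; `σ = Inf`
  disables selection;
* the site's sampling pool mixes all sites' expected vectors with
  weights `exp(−distance / λ)` and, with intensity m, the global mean;
* realized counts are one multinomial draw of J individuals, so J is the
  drift knob: the smaller the community, the larger the share of
  turnover that is pure sampling noise.

One-shot multinomial sampling stands in for temporal drift, which keeps
runtime desk-scale and matches how the null-model literature treats
drift as sampling noise.

### Scenario presets

| preset | σ_sel | φ | λ (km) | m | J | trait |
|---|---|---|---|---|---|---|
| drift | Inf | 1 | Inf | 0 | 5,000 | — |
| heterogeneous_selection | 1 | 1 | 1 | 0 | 100,000 | Brownian, regions offset by 6 env units |
| dispersal_limitation | Inf | 0.2 | 200 | 0 | 100,000 | — |
| homogenizing_dispersal | 1 | 1 | 1 | 0.95 | 100,000 | labile (no phylogenetic signal) |

Three of these choices deserve explanation.

*Community size of the drift preset.*  The Raup-Crick null seeds every
present species with one individual before distributing the rest.  When
richness is a large fraction of community size (S/J ≈ 0.4 at J = 500
with 300 lognormal taxa), that seeding flattens null profiles so much
that *pure multinomial noise* registers as "more similar than null" —
neutral data get labelled homogenizing dispersal.  The framework is
calibrated in the regime it is used in practice, where sequencing depth
vastly exceeds richness; at J = 5,000 (S/J ≈ 0.05) the null's tail rates
for neutral data are at their nominal ~5%.  The drift preset therefore
uses J = 5,000: small enough that sampling noise dominates any signal,
large enough that the null model's seeding approximation holds.

*The selection preset's dispersal scale.*  The mixing step averages
sites' *expected* compositions; with λ = Inf every site's pool becomes
the global mean, which would erase the very selection signal the
parameters create.  The preset uses λ = 1 km, i.e. effectively local
sampling pools, so niche filtering is expressed at the site level.

*The homogenizing-dispersal preset's labile trait.*  Detecting
homogenizing dispersal requires turnover *below* the null expectation
with no overriding βNTI signal.  With selection on a Brownian
(phylogenetically conserved) trait, βNTI correctly reports the residual
selection signal first — that is the selection preset.  And with no
selection at all, every taxon occurs everywhere at J = 100,000, the
observed noise equals the null's, and there is nothing left for RC to
detect.  The regime that genuinely expresses homogenizing dispersal is
site-level environmental filtering on a *phylogenetically labile* trait
(iid optima with the same marginal variance as the Brownian model) —
classic mass effects overriding local selection.  βNTI is, by
construction, blind to selection without phylogenetic signal, the
filtering keeps occupancy unsaturated, and the 95% mixing pushes
observed turnover below the Raup-Crick null.  This is also a useful
reminder of a known limitation of the framework itself: βNTI only
detects selection on phylogenetically conserved niches.

### What the generator does not emulate

Real amplicon data have thousands of OTUs with an excess of rare taxa,
compositional depth variation between samples, PCR/primer biases, and
temporally autocorrelated dynamics.  The generator's communities are
single multinomial snapshots from smooth parametric pools.  Passing the
recovery tests therefore shows that the classifier identifies the
processes *as implemented by this generative model*, not that it is
unbiased on any real dataset.

## Numerical choices

* Rarefaction subsamples reads without replacement and conserves the
  target depth exactly; samples below depth are dropped with a warning.
* Shannon defaults to log base 2; Faith's PD includes the branches
  connecting the present taxa's subtree to the root (both conventions of
  the classic QIIME tooling, both flags).
* PCoA reports negative eigenvalues unmodified and excludes them from
  the proportion explained; a Cailliez correction is available.
* Null standard deviations below 1e-7 of the null mean are treated as
  exactly zero (accumulated-rounding guard) before the degenerate-null
  rules above apply.
* Undefined index values propagate as `NA`, never as zero.
* Every randomized routine takes a seed; the pipeline derives
  deterministic child seeds for each stage from one master seed, and the
  tabular outputs are byte-identical across runs.

## Problem sizes used by the validation suite

The packaged tests validate: exact oracle equality of βMNTD against a
brute-force double loop on 200 random instances (≤ 8 taxa, ≤ 4 samples);
exhaustive-enumeration equality for Mantel (n = 6) and the exact
rank-sum test (n = m = 5); self-calibration of the βNTI and RC nulls on
200 replicate datasets of 8 samples × 40 taxa at 999 randomizations;
5% type-I calibration of the five permutation tests over 1,000 null
simulations at 199 permutations; and recovery of all four presets at 20
samples × 300 taxa × 999 randomizations.  These sizes keep the whole
suite in the minutes range on a single core while leaving each check
statistically meaningful.

## Known limitations

* The five-way classification inherits the thresholds (|βNTI| > 2,
  |RC| > 0.95) from the established framework; they are configurable but
  have no finite-sample optimality guarantee.
* RC_bray is sensitive to the ratio of richness to community size (see
  above); fractions from datasets where S approaches N should be read
  with caution.
* βNTI cannot attribute turnover to selection acting on traits without
  phylogenetic signal; such selection surfaces in the RC step instead.
* The decay regression treats pair non-independence only in the test
  (via sample-identity permutations), not in the point estimates.
* Within one dataset every pair shares the same tree, pool partition and
  metacommunity draws, so βNTI values are correlated across pairs:
  whole-dataset excursions of the βNTI distribution by about ±2 occur
  for a minority of realizations and can flip the modal process of a
  single synthetic dataset.  Process fractions from one dataset are one
  realization, not an expectation over the regime.
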