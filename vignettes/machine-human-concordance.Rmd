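---
title: "Benchmarking machine social annotations against human rater pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking machine social annotations against human rater pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialconcord)
```

## The problem

Large vision-language models can be asked to rate the prominence of social
features ("Talking", "Dominant", "Feeling pleasant", ...) in images and video
clips on a bounded intensity scale. Whether such machine annotations can
stand in for pooled human ratings is an empirical question with three
distinct levels:

1. **Ratings.** Per feature, does the machine's rating track the human
   population average across stimuli at least as well as a single human
   does?
2. **Structure.** Do the machine's annotations carry the same
   representational geometry — the same feature-by-feature correlation
   structure and the same low-dimensional organisation — as the human
   annotations?
3. **Neural encoding.** When the two annotation sources are turned into
   fMRI stimulus models, do they localise the same voxelwise responses?

`socialconcord` implements all three stages as a tested pipeline, together
with synthetic generators that plant known ground truth, so every statistic
can be validated end to end without access to any restricted dataset.

## Stage 1: rating agreement and its human benchmarks

Ratings live in a panel $X_{ifr}$ (item $i$, feature $f$, rater $r$) on a
bounded scale, rescaled affinely to $[0, 10]$ before analysis. All
correlations are Pearson product-moment correlations on pairwise-complete
items, with a minimum of 3 complete pairs (less yields an explicit
`insufficient_pairs` flag rather than a number).

* **Agreement**: $r$ between the machine's mean rating (over collection
  rounds) and the human pool mean, per feature, across items.
* **Intersubject consistency**: for each rater, $r$ between their ratings
  and the mean of all *other* raters; averaged over raters. This is the
  reliability of one randomly drawn human — the natural benchmark, because
  fMRI subjects are single humans modeled with other people's average
  annotations. Raters with undefined correlations (constant ratings) are
  dropped from the mean and counted, not zero-filled.
* **Group consistency**: the pool is split into two disjoint groups of
  $g = 5$ raters in all possible unordered ways ($\binom{10}{5}/2 = 126$
  splits for a 10-rater pool); the two group means are correlated per split
  and averaged. By the Spearman–Brown relation this upper-bounds the
  single-rater benchmark.

Whole-set comparisons use Welch's unequal-variance two-sample $t$-test on
Fisher-$z$ transformed values with two-sided $p$-values. The choice of the
Welch form and the two-sided convention are deliberate defaults where a
pooled-variance or one-sided reading would also have been defensible; both
choices are conservative. Exceedance fractions use strict inequality.

## Stage 2: representational structure

Let $C^{(m)}$ and $C^{(h)}$ be the $F \times F$ feature correlation matrices
of machine and human mean ratings. Their similarity is the Pearson
correlation of the strict upper triangles ($F(F-1)/2$ pairs). Significance
comes from a Mantel permutation test: rows and columns of one matrix are
permuted jointly, and
$p = (\#\{r_\text{null} \ge r_\text{obs}\} + 1)/(n_\text{perm} + 1)$.
The `+1` correction makes the test valid (conservative) at any permutation
count; an exhaustive mode enumerates all $F!$ permutations for $F \le 7$.

The low-dimensional organisation is extracted by principal coordinate
analysis (classical MDS) of the distance $d_{ij} = 1 - r_{ij}$: Gower
double-centering $B = -\tfrac12 J D^{(2)} J$, eigendecomposition, and
coordinates $\lambda_k^{1/2} v_k$ for the $k$ largest positive eigenvalues.
$1 - r$ is used rather than $\sqrt{2(1-r)}$ to stay closest to treating the
correlation itself as the distance; the transform is isolated behind the
`distance` argument. Because $1 - r$ is not guaranteed Euclidean, negative
eigenvalues can occur; they are dropped and counted rather than
magnitude-scaled.

Concordance between two ordinations correlates component loadings across
features for every component pair, reporting $|r|$ (component signs are
arbitrary) with $t$-distribution $p$-values on $F - 2$ degrees of freedom
and a significance mask at $\alpha = 0.001$. Near-degenerate eigenvalues can
swap component order between noisy replicates, so `match_components()`
additionally pairs components greedily by $|r|$ when judging recovery of a
planted dimensionality.

## Stage 3: fMRI encoding comparison

Each feature's item-level intensities become a stimulus model: a boxcar at
microtime resolution (16 bins per TR; a convention, the analysis is
insensitive to it at these TRs) carrying the feature intensity over each
clip's duration, convolved with the canonical double-gamma HRF (response
gamma with shape 6 and scale 1 peaking near 5 s, undershoot gamma with
shape 16 scaled by 1/6, 32 s support, unit peak), sampled at volume onsets
and mean-centred.

First-level analysis is massive-univariate *simple* regression: each
feature regressor is fitted separately per voxel (slope of OLS with
intercept). This mirrors the common practice of separate encoding models
per feature and makes cross-feature collinearity a property of the
interpretation, not of the fit. Group inference is a one-sample $t$-test
per voxel with one-sided $p$ for positive effects, since the comparison
targets positive feature associations. Thresholds: lenient $p < 0.001$
uncorrected and conservative voxel-level FWE at $p < 0.05$ implemented as
Bonferroni over in-mask voxels — a deliberately conservative stand-in for
random-field-theory FWE, which is out of scope.

Two stimulus models are compared by (i) spatial correlation of
unthresholded group beta maps per feature, (ii) PPV/NPV of the machine's
thresholded maps against the human maps as reference, and (iii) the spatial
correlation of the two cumulative maps (per-voxel counts of features
passing the lenient threshold).

## What the synthetic generators emulate

* `simulate_rating_panel()` plants a $K$-dimensional latent structure
  (default $K = 8$, matching the dimensionality repeatedly found in human
  social perception): item scores times feature loadings, mapped affinely
  onto $[0, 10]$ (centre 4, spread 1.8) and clipped. Component scales decay
  geometrically (ratio 0.75) so adjacent planted eigenvalues stay separated
  and the dimensions are mutually identifiable from finite noisy samples.
  Rater noise is Gaussian with clipping; the per-feature noise sd is chosen
  by inverting $c = 1/\sqrt{(1+v)(1+v/(R-1))}$ (with $v$ the noise-to-signal
  variance ratio) so that the expected single-rater consistency matches the
  requested profile. Defaults mirror a typical large annotation study:
  234 items, 136 features, 10 raters, consistency 0.6.
* `simulate_machine_ratings()` adds the empirically motivated *floor bias*
  — values below the scale midpoint 5 are shrunk by a factor
  $1 - \text{floor\_bias}$, values at or above 5 pass unchanged — plus
  Gaussian round noise over 5 collection rounds, and item-level refusals
  (default rate 0.036) that leave an item missing in *every* round.
* `simulate_bold()` generates event-related BOLD at TR 2.6 s over 467
  volumes: sparse positive voxel tuning (default 5% of voxel-feature
  cells), subject-level beta jitter applied to tuned cells only — untuned
  voxel-feature pairs carry no subject-specific response, which keeps
  tuning genuinely sparse — and white temporal noise.
  `calibrate_bold_noise()` picks the temporal noise for a target group-level
  effect size $d$, accounting for the jitter that correlated regressors leak
  into each other's simple-regression betas (expected multiplier
  $1 + \text{tuned\_fraction}\sum_{g \ne f} a_{gf}^2$ with
  $a_{gf} = x_g^\top x_f / \lVert x_f \rVert^2$).

What the generators do **not** emulate: item difficulty structure beyond the
latent model, rater-specific biases or scale use, temporal autocorrelation
and physiological noise in BOLD, spatial smoothness of maps, or any content
of the stimuli themselves. Passing tests therefore demonstrate correctness
of the statistics and the expected qualitative behaviour of the pipeline,
not performance claims about any particular annotator on real data.

One consequence of the clipped affine intensity map is worth noting: the
clipping is a mild nonlinearity shared by all raters *and* replicate pools,
so replicate ordinations of an 8-dimensional truth typically show a weak
but genuine ninth shared component ($|r| \approx 0.5$) before the diagonal
of the concordance matrix vanishes. Recovery of the planted structure is
therefore judged on the matched first eight components and the vanishing of
the diagonal from component ten onward.

## Numerical and degenerate-input conventions

* Undefined correlations (constant input, fewer than 3 complete pairs) are
  `NA` plus a machine-readable flag, never silent zeros, and are excluded
  from means with their counts reported.
* Fisher $z$ clips $|r| \ge 1$ to $1 - 10^{-7}$ with a warning.
* Mantel ties are counted with a $10^{-12}$ tolerance so the identity
  permutation always counts in the exhaustive mode.
* PCoA eigenvalues within $10^{-12}$ of zero (relative) are treated as
  null; requesting more components than positive eigenvalues truncates with
  a warning.
* Zero-variance voxels in group t-maps yield `NA` with a count; empty
  positive/negative sets in PPV/NPV are flagged, not divided by zero.
* All generators take explicit integer seeds; the pipeline derives
  per-stage seeds deterministically from one master seed, so reruns are
  bit-identical.

## Problem sizes used in the built-in checks

The bundled verification suite exercises the statistics at the following
scales, chosen to keep a full run on one CPU within minutes while leaving
the Monte-Carlo assertions well powered: oracle equivalence on panels of at
most 5 items x 4 features x 6 raters; reliability ordering on 50 replicates
of 200 items x 200 features x 10 raters; Mantel calibration on 1000
simulated 20 x 20 matrix pairs with 999 permutations each; planted-structure
recovery on 200 items x 136 features; encoding recovery on 20 subjects x
2000 voxels x 467 volumes with 8 features at $d = 1$; and a demonstration
pipeline (200 items, 50 features, 10 subjects, 500 voxels, 10000 Mantel
permutations) run twice to confirm bit-reproducibility. The acceptance
script runs the study-scale configuration (234 items, 136 features,
1,000,000 Mantel permutations, 20 subjects, 2000 voxels).

## Known limitations

* Group consistency enumerates all splits; this is exact for 10 raters
  (126 splits) but grows combinatorially, so very large pools would need a
  sampling strategy that is not implemented.
* The Mantel permutation loop is pure R; a million permutations on a
  136-feature problem takes on the order of a minute.
* PPV/NPV depend strongly on tuning breadth: with many mutually correlated
  regressors and simple (per-feature) regressions, reference maps become
  broadly positive and NPV is dominated by cross-feature leakage. This is a
  property of the massive-univariate design being emulated, not of the
  implementation.
* NIfTI support covers plain 4-D volumes; no surface formats, no BIDS
  layout discovery.
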