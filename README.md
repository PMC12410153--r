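# socialconcord

Concordance of machine and human social annotations at the rating,
structural, and neural levels.

## The problem

Vision-capable language models can rate the prominence of social features
("Talking", "Dominant", "Feeling pleasant", ...) in naturalistic images and
video clips on a bounded intensity scale. Before such machine annotations
can replace or augment pooled human ratings — for behavioural analyses or
as fMRI stimulus models — their concordance with human rater pools has to be
quantified. `socialconcord` is an R package for exactly that benchmark,
aimed at researchers in social perception and naturalistic neuroimaging. It
evaluates an annotator at three levels:

1. **Rating agreement.** Per feature $f$, the agreement index
   $r_f = \mathrm{cor}\big(\bar m_{\cdot f},\, \bar h_{\cdot f}\big)$
   between the machine mean (over collection rounds) and the human pool
   mean across items, benchmarked against
   - *intersubject consistency*: the mean over raters of
     $\mathrm{cor}(x_{\cdot f r},\, \bar h^{(-r)}_{\cdot f})$, each rater
     against the mean of all others (the reliability of one human), and
   - *group consistency*: the mean correlation between the mean ratings of
     two disjoint groups of 5 raters over all $\binom{10}{5}/2 = 126$
     splits (the reliability of a small pool),
   with Welch two-sample t-tests on Fisher-z values across features and
   strict exceedance fractions.
2. **Representational structure.** Pearson similarity of the two $F \times
   F$ feature correlation matrices over their strict upper triangles,
   tested with a seeded Mantel permutation test
   ($p = (\#\{r_{\mathrm{null}} \ge r_{\mathrm{obs}}\}+1)/(n+1)$); principal
   coordinate analysis (classical MDS, Gower double-centering of
   $d = 1 - r$) of each matrix; and the concordance $|r|$ of component
   loadings with $t$-based p-values ($df = F - 2$, $\alpha = 0.001$).
3. **Neural encoding.** Each feature becomes a stimulus model (boxcar at
   16 microtime bins per TR, canonical double-gamma HRF, mean-centred),
   fitted voxelwise as independent simple regressions; group one-sample
   t-maps (one-sided, positive) are thresholded at $p < 0.001$ uncorrected
   and voxel-level Bonferroni FWE $p < 0.05$. Models are compared via
   spatial correlations of unthresholded group betas, PPV/NPV against the
   human-derived maps, and the correlation of cumulative social-tuning
   maps.

Seeded synthetic generators (rater pools with a planted 8-dimensional
latent structure and calibrated reliability, multi-round machine annotators
with a low-end "floor" bias and item refusals, and event-related BOLD with
sparse voxel tuning) provide known ground truth so the whole pipeline is
testable offline.

## Worked example

The demonstration configuration simulates 200 items x 50 features x 10
human raters with single-rater consistency 0.6, a 5-round machine annotator
with floor bias 0.2 and 3.6% refusals, and a 10-subject, 500-voxel BOLD
experiment; it runs all three stages:

```r
library(socialconcord)
res <- run_pipeline(default_config(demo = TRUE, seed = 42))
print(res)
#> <pipeline_result>
#> <agreement_report>
#>   features: 50   overall r (pooled cells): 0.917
#>   mean agreement: 0.910 | intersubject: 0.596 | group-of-5: 0.778
#>   agreement > intersubject for 100% of features; > group for 100%
#> <structure_report>
#>   correlation-matrix similarity r = 0.996 (Mantel p = 0.0001, 10000 permutations)
#>   significant diagonal loading correlations: 8 of 13 components
#> <encoding_comparison>
#>   features: 50  mean spatial r: 0.995  cumulative-map r: 0.980
#>   mean PPV 0.986 / NPV 0.864 (p < 0.001 unc.); PPV 0.974 / NPV 0.909 (FWE 0.05)
```

Reading the output: the simulated machine tracks the human average better
than any single human (mean agreement 0.91 vs intersubject consistency
0.60) and, in this noiseless-bias regime, better than groups of five
(0.78); the realised single-rater consistency 0.596 confirms the
generator's reliability calibration (target 0.6). The two correlation
matrices are nearly identical in structure (similarity 0.996, Mantel
p = 1e-4, the smallest value 10,000 permutations can resolve), and the
planted 8-dimensional structure appears as exactly 8 strong diagonal
loading correlations. At the neural level the machine- and human-derived
stimulus models localise near-identical responses (mean spatial r 0.995;
cumulative-map r 0.98).

Individual stages are plain functions on data frames / panels —
`read_rating_table()`, `agreement_report()`, `structure_report()`,
`fit_encoding()`, `compare_encodings()` — with `tidy()`, `glance()` and
`autoplot()` methods on every report object. `run_pipeline(cfg, out_dir =
"out")` additionally writes all TSV/JSON artifacts and a reproducibility
manifest; reruns with the same config are bit-identical.

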