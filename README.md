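# grimkit

Criterion importance and severity analysis for Mouse Grimace Scale (MGS)
studies with repeated interventions.

The MGS rates pain in mice on five facial action units (FAUs) — orbital
tightening (OT), nose bulge (NB), cheek bulge (CB), ear position (EP),
whisker change (WC) — each scored 0/1/2 per video frame and summed into a
composite score. Scoring five criteria per frame is slow, and some criteria
are unreliable to rate, so a central welfare-assessment question is whether
the scale can be simplified to its most informative criterion. grimkit
answers it two independent ways and then quantifies injection-induced pain
through the winning criterion:

* **Coalition importance.** Every non-empty subset `S` of the five criteria
  gets a measure `M(S)`: the rank-based effect size `r = |z|/sqrt(N)` of the
  pre- vs. post-injection contrast on the composite score
  `sum_{k in S} score_k` (Cliff's delta available). All 31 subsets are
  ranked by `M/M_max`, and each criterion's contribution is attributed by
  the exact Shapley value
  `phi_i = sum_{S ⊆ N\{i}} |S|!(n-|S|-1)!/n! (v(S+i) - v(S))`.
* **Penalized regression.** The average picture score is regressed on the
  scaled criteria and their week/intervention interactions per treatment
  arm (LASSO, 10-fold CV, one-standard-error rule); coefficients at
  `lambda_1SE` are ranked by magnitude.
* **Mixed models, severity, bootstrap.** Orbital tightening is modelled
  with REML random-intercept models (between treatments; within each arm),
  discretized into mild (< 3) / moderate (3–6) / severe (> 6) classes with
  Pearson chi-squared tests and FDR-adjusted pairwise post-hocs, and
  summarised as 10,000-fold bootstrap medians with percentile confidence
  intervals plus Mann–Whitney contrasts.

A calibrated synthetic-data generator emulates the full study design
(two arms x 12 animals, weeks 0–4, 3 injection days/week, pre/post videos,
8 frames/video, ~15% frame rejection, ~23% missing videos) with a planted
importance ordering, so the entire pipeline is testable end to end without
access to the original recordings.

## Worked example

```r
library(grimkit)

ds <- emulate_study(seed = 1)   # synthetic study preset, aggregated per video
ds
#> MGS video-level dataset: 496 records, 24 animals (aggregation: scaled_sum)

single_fau_ranking(rank_combinations(ds))
#>   subset          M      M_rel
#> 1     ot 0.55565454 0.99405239
#> 2     ep 0.20397517 0.36490659
#> 3     nb 0.18784556 0.33605112
#> 4     cb 0.10237917 0.18315383
#> 5     wc 0.01717453 0.03072481
```

Orbital tightening is the most discriminative single criterion (its `M` is
within 1% of the best coalition overall) and whisker change the least —
recovering the ordering the generator planted. The independent regression
route agrees:

```r
mgs_lasso(ds, "CCl4", seed = 1)
#> L1-penalized criterion regression (CCl4)
#>   n = 212, 10-fold CV (seed 1): lambda_min = 0.02394, lambda_1se = 0.1061
#>   nonzero coefficients at lambda_1se (|beta| descending):
#>     name   beta
#>       ot 0.2470
#>       ep 0.1406
#>       cb 0.1174
#>  nb:post 0.0475
#>       nb 0.0118
```

The mixed model of orbital tightening within the CCl4 arm shows the
injection effect: a post-injection video scores about 2.9 units higher than
the pre-injection video of the same week (0–16 scale), with animal identity
explaining 46% of the variance in this synthetic dataset:

```r
fit_ot_model(ds, "II")
#> Mixed-effects model II (within-treatment CCl4), REML, 212 records / 12 animals
#>              term estimate    se      df ci_low ci_high     p
#>       (Intercept)    3.117 0.552  20.582  1.967   4.267 0.000
#>  interventionpost    2.911 0.474 193.236  1.977   3.845 0.000
#>  ...
#> Variance components: tau_animal_id = 2.491; sigma2 = 2.891; ICC = 0.463

mann_whitney_contrast(ds, list(treatment = "CCl4", week = 0),
                      list(treatment = "CCl4", week = 1, intervention = "post"))
#> W = 116.5, z = -3.900, r = 0.546, Cliff's delta = -0.638 (n1 = 28, n2 = 23, p = 9.638e-05)
```

Severity statistics work on any count table; on the published 3x3 severity
tables they reproduce the reported statistics exactly:

```r
ccl4 <- matrix(c(8, 12, 0, 49, 54, 3, 9, 69, 13), nrow = 3, byrow = TRUE,
               dimnames = list(c("bsl", "pre", "post"),
                               c("mild", "moderate", "severe")))
chi_square(ccl4)[c("statistic", "df", "p")]
#> $statistic [1] 37.15  $df [1] 4  $p [1] 1.68e-07
```

`run_mgs_pipeline()` executes all stages in order and returns one
reproducible report object; `write_report()` serialises it to JSON and CSV
(identical seeds give byte-identical files). External per-frame data in the
same layout are ingested with `read_image_scores()` (a `column_map` adapts
arbitrary headers) and flow through the identical path.

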