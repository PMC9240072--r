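---
title: "Ranking grimace-scale criteria and quantifying injection pain with grimkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking grimace-scale criteria and quantifying injection pain with grimkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(grimkit)
```

## The scientific problem

The Mouse Grimace Scale (MGS) scores pain in mice from facial expression.
Five facial action units (FAUs) — orbital tightening (OT), nose bulge (NB),
cheek bulge (CB), ear position (EP) and whisker change (WC) — are each rated
0 (no deviation), 1 (moderate) or 2 (severe) on still frames taken from
video, and the ratings are summed into a composite pain score. Scoring five
criteria on every frame is laborious and some criteria (whisker change in
particular) are hard to rate reliably, which motivates asking: *do all five
criteria carry equal information, and could the scale be simplified to its
most informative criterion?*

grimkit implements the analysis pipeline for a repeated-intervention study
design: two treatment arms (a hepatotoxic CCl4 injection vs. an oil vehicle
control, 12 animals each), intraperitoneal injections three times per week
over four weeks, video taken one hour before (`pre`) and one hour after
(`post`) each injection, plus an uninjected baseline week (`bsl`, week 0),
with eight frames scored per video. The pipeline

1. aggregates per-frame ordinal scores into per-video records,
2. ranks all 31 non-empty criterion subsets by a coalition effect-size
   measure with exact Shapley attribution,
3. independently ranks criteria by L1-penalized regression coefficients,
4. models orbital tightening with random-intercept mixed models,
5. discretizes scores into severity classes with chi-squared and post-hoc
   tests, and summarises score development with bootstrap median confidence
   bands and Mann–Whitney contrasts.

## Per-video aggregation

Raw data are per-frame scores; a frame can be rejected for a criterion
(coded −1) when it cannot be rated. `aggregate_videos()` collapses the
frames of one video (one animal × week × day × intervention) into a record.
The default per-criterion score is the `scaled_sum`: the mean over accepted
frames times the nominal frame count of 8, i.e. a rejection-unbiased total
on a 0–16 scale. This scale is the one the severity thresholds (3 and 6)
and the mixed-model coefficients presume; per-frame means (`mean`) and raw
sums over accepted frames (`sum`) are retained as options so an analysis of
external data can adjudicate the aggregation empirically. The average
picture score — the response of the penalized regression — is the mean,
over frames with *all five* criteria accepted, of the per-frame sum of the
five scores (0–10); frames with any rejected criterion are excluded rather
than imputed. A video in which some criterion has no accepted frame at all,
or no frame is fully scored, is dropped with a warning and counted.

## The coalition importance measure

For a criterion subset $S$ the composite score of a record is
$\sum_{k \in S} \text{score}_k$. The measure $M(S)$ is the rank-based effect
size of the pre- vs. post-injection contrast on that composite — by default
$r = |z|/\sqrt{N}$ from the tie-corrected normal approximation of the
Mann–Whitney statistic, with Cliff's delta available as an alternative.
Being rank-based, $M$ is invariant to positive rescaling of the scores and
comparable across group sizes and distributions. The default contrast is
pre vs. post within the CCl4 arm over weeks 1–4, where an intervention
effect is expected; pooling both arms is available by configuration since
either choice is defensible.

All $2^5-1 = 31$ subsets are scored and normalized to the maximum
($M_{rel} = M/M_{\max}$). Each criterion's contribution is attributed by
the exact Shapley value
$$\phi_i = \sum_{S \subseteq N\setminus\{i\}}
  \frac{|S|!\,(n-|S|-1)!}{n!}\,\bigl(v(S\cup\{i\}) - v(S)\bigr),$$
enumerated over all 32 subsets (no sampling approximation is needed at
$n = 5$). Within each ranked subset the member weights are the Shapley
values of the sub-game restricted to that subset, normalized to sum to one.
The implementation is validated in the test suite against brute-force
averaging over all 120 player orderings and against the efficiency,
symmetry, dummy-player and additivity axioms.

## The penalized-regression ranking

Independently of the coalition measure, the average picture score is
regressed on the five (strongly collinear) criterion scores and their
interactions with week and with the post-intervention indicator — 15
predictor columns, all standardized to zero mean and unit variance so the
coefficient magnitudes are comparable. Week 0 is excluded because the
intervention variable is constant there (the design would be rank
deficient), and week enters the interactions as numeric 1–4 by default (a
categorical option exists; the two-way interactions stated above are the
only interactions fitted). The L1 path ($\alpha = 1$) is computed by
glmnet over a 100-point log-spaced grid from the smallest penalty that
zeroes all coefficients down by a factor $10^{-4}$; 10-fold cross-validation
with a seeded fold assignment selects $\lambda_{1SE}$, the largest penalty
whose CV mean squared error is within one standard error of the minimum.
Coefficients at $\lambda_{1SE}$ are ranked by absolute value, per treatment
arm. Fold assignment is the only stochastic element and is controlled by a
seed; the reported $\lambda_{1SE}$ therefore varies between fold draws, and
no particular value of it is asserted.

## Mixed-effects models of orbital tightening

Three REML random-intercept models take the per-video OT score as response:

* **Model I** (between treatments, all weeks): fixed effects treatment,
  intervention, day and their pairwise interactions; random intercepts for
  animal and for day nested in week. Reference levels Oil / pre / day 1.
* **Model II** (within CCl4, weeks 1–4): fixed effects week (categorical,
  reference week 1), intervention and their interaction; random intercept
  for animal.
* **Model III**: as II for the Oil arm.

Variance components $\tau$, the residual variance $\sigma^2$, percentage
variance shares and the intra-class correlation
$\mathrm{ICC} = \sum\tau / (\sum\tau + \sigma^2)$ are reported. Confidence
intervals and p-values use Satterthwaite degrees of freedom via lmerTest;
the Kenward–Roger correction used in some published analyses is a close
relative but is not available here, and the choice affects only inference,
never the point estimates — a normal-approximation fallback is provided.
Singular fits (a variance component estimated at zero) are returned with a
boundary flag rather than an error.

## Severity classification and the surrounding statistics

Aggregated scores are discretized as mild (< 3), moderate (3–6, boundaries
inclusive) or severe (> 6). Counts per treatment × intervention × class
feed a Pearson chi-squared test (no continuity correction; with the printed
3 × 3 count tables of the source study this reproduces the published
statistics 37.15 and 10.579 exactly, which is how the no-correction choice
was adjudicated). Pairwise class post-hocs compare the intervention
profiles of each class pair by the same chi-squared test with FDR
adjustment; this scheme reproduces the control arm's published adjusted
p-values (0.044 / 0.285 / 0.627) to the printed precision. Pairs with
expected counts below 5 are flagged, and Fisher's exact test can be
requested instead — it is not the default precisely because the published
values reproduce only under the plain chi-squared test.

Score development is summarised by bootstrap medians: resampling with
replacement (default 10,000 resamples, seeded), percentile 2.5/97.5
intervals, reported per treatment × week × intervention stratum with days
pooled within week. Baseline and week-1 contrasts use the same
Mann–Whitney machinery as the coalition measure (W in the first-sample
convention, so published W values are directly comparable). Normality
checks (Shapiro–Wilk with quantile–quantile pairs) motivate the
distribution-free choices: per-video ordinal totals are grossly
non-Gaussian.

## The synthetic-data generator

`simulate_mgs()` emulates the study design so every downstream stage can be
tested end to end without the original recordings. Per video, a latent pain
level is drawn:
$$L = a_i + \beta_T\,[\text{CCl4}] +
      (\beta_I + \beta_{IC}\,[\text{CCl4}])\,[\text{post}] +
      \beta_w\,\text{week} + \eta,$$
with animal intercepts $a_i$ (SD 0.25) and video noise $\eta$ (SD 0.1).
Per frame, each criterion $k$ observes
$X_k = s_k L + c\,(\sqrt{\rho}\,G + \sqrt{1-\rho}\,e_k)$, where $G$ is a
frame factor common to all criteria ($\rho = 0.45$, total frame noise
$c = 0.6$), and $X_k$ is cut into 0/1/2 at thresholds $0.45/1.7$ plus a
per-criterion expressiveness shift. The intervention raises pain in both
arms ($\beta_I = 0.06$: the injection itself hurts) with a CCl4-specific
increment ($\beta_{IC} = 0.28$); the treatment shift ($\beta_T = 0.11$)
applies in all weeks, so the arms differ already at baseline, and a small
weekly trend (0.012) accumulates over the four treatment weeks.

The planted importance ordering works through two mutually reinforcing,
realistic mechanisms: the *loading* $s_k$ (OT 1.6 > EP 0.6 > CB 0.52 >
NB 0.42 > WC 0.03) and the *expressiveness shift* (OT −0.12 … WC +0.9 —
orbital tightening is scored nonzero often, whisker change rarely, which
matches how raters behave). Frames are rejected independently per criterion
(probabilities 0.10–0.22, highest for whisker change, ~15% overall) and
whole videos are missing with probability 0.232, so the default preset
yields about 496 records for 24 animals — the shape of the real dataset.
One master seed drives everything; per-animal substreams are derived by
fixed offsets so adding animals does not perturb existing ones.

### What the generator does and does not emulate

It reproduces the design (arms, weeks, days, pre/post videos, 8 frames,
rejections, missing videos), ordinal marginals with a mild-leaning
baseline, positive inter-criterion correlations, and a recoverable
importance ordering with OT most and WC least discriminative. Three
deliberate deviations from the source study's summary statistics are worth
knowing about:

* **Residual variance.** With eight conditionally independent ordinal
  frames per video, the per-video total has a discreteness variance floor
  of about 3 score units² — roughly double the residual variance trained
  raters achieve (raters score the frames of one video consistently).
  Matching the published raw intervention coefficient (≈1.7) at this noise
  level would halve the standardized effect, so the generator matches the
  *standardized* effect instead: synthetic Model II intervention
  coefficients come out near 2.5–3 raw and the baseline-vs-post effect size
  $r \approx 0.5$.
* **Inter-criterion correlations.** In the real data all ten pairwise
  correlations are high (0.57–0.90) because a scorer-session factor affects
  all criteria equally. A common factor that strong makes the
  criterion–response correlation non-monotone in the pain loading, i.e. it
  erases the very structure the importance analyses are tested on. The
  generator therefore uses a moderate common factor; synthetic correlations
  are positive but mid-strength, weakest for the whisker-change pairs.
* **Severity mix under strong effects.** The post-intervention CCl4 videos
  land in the severe class more often than the published distribution;
  this is the flip side of matching standardized effects at the higher
  noise floor.

Consequently, passing tests demonstrate correctness of the estimators and
recoverability of a planted structure under the study design — not that
real scorings have these exact second moments.

## Numerical and design choices

* Coalition measure ties: the Mann–Whitney variance uses the midrank tie
  correction; two identical constant samples define $z = 0$, $r = 0$.
* `subset_key()` identifies coalitions by sorted labels joined with `+`;
  the empty set is `"{}"` because R cannot index by an empty name.
* Shapley weights of a zero-valued subset are reported as equal shares.
* LASSO: the grid and the 1-SE rule are owned by the package; glmnet only
  solves the path (`thresh = 1e-10`); at zero penalty the path agrees with
  ordinary least squares to 1e−6 (tested).
* Mixed models: bounded REML via lme4; $\tau \ge 0$ by construction;
  boundary fits are flagged, not errored.
* Bootstrap: the estimate is the median of the bootstrap distribution, so
  the ordering `ci_low ≤ median ≤ ci_high` holds by construction.
* Chi-squared preconditions: a zero row or column marginal is an error
  naming the offending margin.
* Determinism: every stochastic stage (simulation, CV folds, bootstrap)
  takes an explicit seed, and `run_mgs_pipeline()` records all of them in
  the report; identical configuration and seeds give byte-identical JSON.

## Problem sizes used in the checks

The test suite validates the estimators against independent oracles at
deliberately small sizes: 100 random 5-player games against brute-force
permutation averaging; 100 two-sample draws against an $O(n_1 n_2)$ pair
count; 100 datasets simulated from the random-intercept model (12 animals,
288 records each) for parameter recovery; 500 Gaussian samples of size 30
(1,000 resamples each) for bootstrap coverage; and 100 generator replicates
for recovery of the planted importance ordering (observed: Kendall
$\tau \ge 0.8$ in 91/100, OT ranked first in 99/100 — frozen as regression
bars). The full pipeline runs use the default preset (~496 records).

## Known limitations

* The exact per-video aggregation used for the published 0–16 score scale
  is not documented; `scaled_sum` is the package's reasoned default and the
  alternatives are one argument away.
* Kenward–Roger degrees of freedom are approximated by Satterthwaite.
* The generator trades second-moment fidelity for recoverable structure,
  as described above.
* The coalition analysis is specialized to five criteria with exact
  enumeration; it does not implement sampling-based Shapley approximations
  for larger criterion sets.
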