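---
title: "Methods: personalized advantage index estimation and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized advantage index estimation and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and algorithms, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, the numerical choices,
and the known limitations. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Outcome model: calculated change scores

Repeated symptom scores (CAPS-5 and PCL-5, both 0–80) at weeks 0, 4, 8, 16
are reduced to one *calculated change* per patient and instrument via a
linear growth model fitted separately per treatment group (pooled exposure
arms PE + iPE, and STAIR+PE) and instrument:

$$y_{it} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t + \varepsilon_{it},
\qquad (b_{0i}, b_{1i}) \sim N(0, G),\ \varepsilon_{it} \sim N(0, \sigma^2)$$

with time $t$ in calendar weeks, identical for all arms (the intensified arm
compresses *sessions*, not the assessment schedule). Estimation is maximum
likelihood (`lme4::lmer`, `REML = FALSE`): the product is per-patient
prediction, not variance inference, and ML keeps the fixed and random parts
internally consistent for that purpose. The calculated change is

$$\Delta_i = y_{i0}^{\text{obs}} - \left[(\hat\beta_0 + \hat b_{0i}) +
16(\hat\beta_1 + \hat b_{1i})\right],$$

higher = larger symptom decrease. Two baseline conventions are supported:
the default uses the observed week-0 score (the literal reading of
"baseline score minus predicted posttreatment score"); `baseline = "model"`
substitutes the model-implied baseline $\hat\beta_0 + \hat b_{0i}$, giving a
fully model-based change whose variance is not inflated by week-0
measurement error (but is deflated by BLUP shrinkage — see §6).

Singular fits fall back in documented steps (correlated → independent random
effects → random intercept only, each with a warning); a zero-variance
response short-circuits to the exact flat fit. Patients lacking a week-0
measurement are excluded from observed-baseline change scores with a
warning.

A point worth stating because it is easy to over-expect: the conditional
(empirical-Bayes) slope of a patient is *not* guaranteed to lie between the
population slope and the patient's own least-squares slope. With uncentered
time the shrinkage matrix $G\,(G + \sigma^2 (Z^\top Z)^{-1})^{-1}$ has
off-diagonal terms, so intercept deviations leak into conditional slopes.
The test suite pins the conditional effects to the exact generalized-least-
squares solution instead, and asserts the shrinkage facts that do hold
(reduced spread, no amplification beyond the most extreme deviation).

## 2. All-relevant predictor screening with shadow features

Per group and instrument, the 24 baseline predictors are screened against
the calculated change with a from-scratch shadow-feature loop:

1. append one freshly permuted *shadow* copy of every surviving predictor;
2. fit a random regression forest (`randomForest`; defaults: 500 trees,
   `mtry = ceiling(p/3)` of the augmented design, unrestricted depth) and
   compute per-column importance Z-scores — the mean over trees of the
   out-of-bag MSE increase after within-tree permutation, divided by its SD
   over trees (degenerate spreads map to the sentinels $\pm\infty$ and 0);
3. record a *hit* for every original strictly above the maximum shadow Z;
4. test each undecided predictor's hit count against Binomial(rounds, ½):
   one-sided upward for confirmation, one-sided downward for rejection, each
   Bonferroni-corrected by the total number of candidates (`alpha = 0.01`
   default); rejected predictors and their shadows leave the design;
5. stop when nothing is tentative or after `max_rounds` (default 1000).

Two deliberate choices: the outcome is continuous, so a regression forest
with OOB-MSE permutation importance replaces the classification wording of
the screening idea — the Z-score formula transfers verbatim. And the
correction is over the *full* candidate set: correcting only over the
currently undecided set lets the sequential per-round test confirm
chance-correlated noise once few candidates remain (we measured ~27% of
pure-noise datasets acquiring a false confirmation under that variant).

What the procedure can and cannot promise at $n \approx 100$: a fixed
dataset column whose realized values happen to carve the (fixed) outcome
well is *persistently* informative in-sample, while the shadows' luck
re-randomizes every round. Such columns — often with near-zero linear
correlation — are confirmed in roughly a quarter to a third of pure-noise
datasets of this size. This is intrinsic to all-relevant selection on one
dataset, not a bug; downstream, the stepwise-AIC refinement and the
bootstrap stability report are the guards against carrying such predictors
into the final model. Predictors still tentative at `max_rounds` are dropped
by default; `keep_tentative = TRUE` admits them to the refinement stage,
which is the package's recommended setting for small samples where
confirmation power is limited (the stepwise stage then does the pruning).

## 3. Stepwise AIC with bootstrap stabilization

Candidates surviving the screen enter a greedy stepwise search (default:
both directions, starting from the full candidate model) under the Gaussian
AIC convention

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(p + 2),$$

counting the intercept and error variance as parameters; moves are taken
only if they strictly lower the AIC, with ties broken toward smaller models,
then lexicographically. On ≤ 10 candidates the search provably matches an
exhaustive all-subset oracle in the test suite. `bootstrap_stepwise()`
reruns the search on `B = 100` row resamples and reports per-candidate
selection frequency and sign consistency. The default final model is the
full-data stepwise model with the bootstrap attached as a diagnostic; a
`frequency_threshold(tau)` rule (keep candidates selected in ≥ `tau` of
resamples, refit OLS) is available because the conventional description of
the procedure is ambiguous between the two.

## 4. Counterfactual predictions and the PAI

Variable selection is performed once on the full sample and frozen; only the
OLS coefficients vary across leave-one-out folds. For patient $i$ in group
$g$: the received-group prediction comes from the group-$g$ model excluding
$i$ (computed by the exact hat-matrix identity
$\hat y_{(i)} = \hat y_i - h_{ii} e_i / (1 - h_{ii})$, which the tests pin
to a naive per-fold refit at $10^{-9}$), and the alternative-group
prediction from the full other-group model. Then

$$\mathrm{PAI}_i = \hat\Delta_i(\text{exposure}) -
\hat\Delta_i(\text{STAIR+PE}),$$

positive recommending exposure. A PAI of exactly zero carries no evidence to
switch: the received arm counts as optimal and the tie is logged (a seeded
random tie-break is available). Prediction accuracy is summarized as the
mean and SD of the *absolute* LOO error per group — signed errors average
toward zero and would not produce meaningful error summaries.

## 5. Evaluation

Optimal vs suboptimal patients are compared on the calculated change:
group means and sample SDs, one-way ANOVA $F(1, n-2)$, and Cohen's
$d = (\bar\Delta_{\mathrm{opt}} - \bar\Delta_{\mathrm{sub}})/s_p$ with the
large-sample CI $d \pm 1.96\,\mathrm{SE}(d)$,
$\mathrm{SE}(d)^2 = 1/n_1 + 1/n_2 + d^2/(2(n_1+n_2))$; a noncentral-t CI is
available behind `ci = "noncentral"`. The exact two-group identity
$F = d^2 n_1 n_2 / (n_1 + n_2)$ is asserted in the tests at $10^{-9}$.

The contrast is evaluated *in-sample*, reproducing the retrospective design
this analysis style uses, and that matters for interpretation: the optimal
flag is derived from models trained on the very change scores being
compared. With no true differential response at all, the flag aligns with
whichever group happened to improve more (with intercept-only prediction
models the flag *is* the group indicator, oriented by the observed mean
difference), so the estimated $|d|$ under the null is biased away from zero
— roughly $|N(0, \sqrt{1/n_1 + 1/n_2})|$ plus selection optimism, i.e.
$|d| \gtrsim 0.2$ in a quarter or more of null datasets at $n = 149$. Every
report and summary therefore carries an explicit optimism caveat; a
prospective or held-out evaluation is outside this package's scope.

## 6. The synthetic cohort generator

The generator emulates the restricted source trial as study conditions, not
as a fit to data:

* **Design**: 149 patients randomized 48/51/50 to PE/iPE/STAIR+PE; 24
  baseline predictors with the published per-group means/SDs (or
  proportions) and instrument ranges; assessments at weeks 0/4/8/16 with
  post-baseline values missing completely at random (default rate 0.10 —
  the growth model's "all available measurements" tolerates exactly this).
* **Predictors**: sampled independently per arm. Continuous scales use a
  truncated normal whose parent parameters are solved so the *truncated*
  moments equal the published ones; where no truncated normal can attain
  them (floor-hugging dissociation scores; childhood-trauma subscales whose
  SD exceeds what any truncated normal admits on a 5–25 range) a scaled
  beta matched to the same two moments is used. Binary predictors are
  Bernoulli; the axis-1 diagnosis count is a 0–10-truncated Poisson with
  mean matched. The published moments are thus recovered by construction
  (tested at 3 standard errors with 5,000 per arm). Predictor
  intercorrelations are not published and are left at zero by default —
  a transparency-over-realism choice.
* **Outcomes**: patient-level latent baselines (shared severity offset
  `sd_random_intercept = 6` plus instrument-specific spread; CAPS-5 baseline
  mean 41.4, PCL-5 45), linear latent trajectories whose 16-week improvement
  is `arm_mean_change` plus the planted interactions, patient slope
  heterogeneity `sd_random_slope = 0.3` points/week shared across
  instruments (PCL-5 adds `sd_slope_pcl5 = 0.12` — the two instruments are
  parallel readouts of one latent improvement), occasion noise
  `sd_residual = 5`, scores clipped to 0–80. The outcome baseline is
  generated from `baseline_mean`/`baseline_sd`, *independently* of the
  sampled baseline-severity predictor column — a deliberate simplification
  that keeps the degenerate all-variances-zero contract exact (flat
  trajectories at `baseline_mean`).
* **Planted truth**: `interaction_effects` maps predictor →
  (effect on exposure improvement, effect on STAIR+PE improvement) in
  points per SD of the predictor (standardized against the midpoint of the
  published group moments). The truth table records each patient's
  counterfactual improvement under every arm; `planted_pai()` and
  `planted_contrast()` expose the implied true advantage and the true
  optimal-assignment effect size, the latter either on the latent
  improvement or re-expressed on the calculated-change scale (the scale the
  pipeline estimates on — the honest scale for recovery comparisons, since
  observed-baseline change scores carry week-0 measurement error in the
  denominator while model-based ones are shrunken).
* **The `"paper"` preset** plants interactions sized from the published
  final prediction models (estimate × predictor SD): BDI −2.5, MOS +2.4,
  axis-1 count −1.6, sexual-abuse score −1.3 points/SD on the exposure side;
  EQ-5D +1.6, DERS −2.1, baseline severity −2.5 on the STAIR+PE side; group
  mean improvements 21.38/20.13 (CAPS-5) and 25.82/20.16 (PCL-5). One
  interaction map serves both instruments. Variance components were chosen
  once to land near the published change-score SDs (~7–8 points).

What passing tests on this generator do **not** show: robustness to
correlated predictors, informative dropout, nonlinear trajectories,
item-level measurement structure, or instrument-specific moderator effects —
none of which the generator produces.

## 7. Problem sizes and numerical choices

Interactive defaults are 500-tree forests, `max_rounds = 1000` and
`B = 100`. The shipped test suite and acceptance script run desk-scale
versions chosen once for the package's simulation studies: 100–150-tree
forests with 25–45 selection rounds and `B ≤ 50` in the 100-seed studies,
and 300 trees / 100 rounds / `B = 50` in the end-to-end acceptance run.
Selection decisions depend on within-round comparisons, which stabilize
well below 500 trees; the power of the screen at these sizes is itself
measured in the acceptance suite (≈ 97% for a 0.5-standardized effect at
n = 99).

The recovery study plants one moderator per group at ±2.3 points/SD — the
strength at which the true optimal-assignment contrast on the latent
improvement is 0.5 SD for this symmetric two-moderator design (contrast
$= 2\delta/\sqrt{\pi}$ against within-flag SD
$\sqrt{0.682\,\delta^2 + (16\,s_b)^2}$). The sign-propagation study plants
two moderators per group at ±7 points/SD: its question is whether signs
survive the screening → stepwise → final-model path, so the signals are
sized to be clearly recoverable at both n = 99 and n = 50. The recovery
analysis admits tentative predictors to the refinement stage
(`keep_tentative = TRUE`), the package's recommended small-sample setting.

Other numerics: stepwise ties resolve toward smaller models then
lexicographic order with a $10^{-10}$ tolerance; rank-deficient designs
error naming the collinear columns (bootstrap resamples redraw up to 5
times, then skip with a warning); the LOO identity is exact, so no fold
refitting occurs; all stage randomness descends from one master seed via
deterministic substreams, and rerunning with the same seed and config
reproduces every artifact byte-for-byte.

## 8. Known limitations

* In-sample evaluation overstates the benefit of PAI-guided assignment
  (§5); the package reports it because that is the design it implements,
  with the caveat attached to every summary.
* Selection is frozen before the leave-one-out stage. Refitting the entire
  selection inside each fold would be the stricter cross-validation; the
  frozen reading matches per-patient coefficient (not variable-set)
  variation and is flagged as an optimism source.
* All-relevant screening at n ≤ 100 confirms persistent chance structure in
  a substantial minority of null datasets (§2); treat confirmed sets as
  candidates with stability diagnostics, not as inference.
* The generator samples predictors independently and shares one moderator
  map across instruments; both are simplifications the user can override
  (`interaction_effects`, user-supplied catalogs) but are the defaults.
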