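---
title: "Methods: individual survival distributions for breast-cancer-onset prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual survival distributions for breast-cancer-onset prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`bcaisd` builds and evaluates models that predict, for a healthy woman,
her *individual survival distribution* (ISD) for breast-cancer onset
(BCaO): a curve giving the probability of remaining cancer-free at every
future time, computed from lifestyle and health-history questionnaire
features. From the curve one reads off single-time probabilities, a
predicted median onset time, and — by editing one actionable feature and
re-predicting — the model's counterfactual estimate of how many
cancer-free months a lifestyle change buys.

The intended data are prospective-cohort questionnaires: one row per
subject with follow-up time in months, an event indicator (1 = onset,
0 = censored), and up to 122 mixed numeric/categorical features in four
blocks (baseline, health and lifestyle, diet history, past-year physical
activity), each flagged *actionable* (diet, supplements, activity, social
indices — 98 features) or *intrinsic* (age, menarche age, medical history
— 24 features). Cohorts of this kind are access-restricted, so the
package ships a synthetic generator that emulates the structure such an
analysis assumes, together with a closed-form oracle for testing.

## The pipeline

The analysis is a three-step pipeline, each step fitted on training folds
only:

1. **Missing-value imputation** — median/mode, k-nearest-neighbour
   (k = 2), or deterministic chained equations;
2. **Censored-data feature selection** — univariate Cox Wald screening at
   p < 0.001, recursive feature elimination to 10 features, mRMR with a
   concordance relevance score to 10 features, or elastic-net Cox with the
   mixing ratio chosen by internal cross-validated C-index (plus a
   no-selection arm);
3. **An ISD model** — multi-task logistic regression (MTLR), implemented
   in full here, alongside Cox/Breslow, elastic-net Cox and parametric
   AFT baselines; five further model families (RSF, GBCM, CW-GBCM,
   DeepHit, DSM) are registry adapter slots that produce explicit skip
   records until a constructor is registered, keeping the
   3 × 5 × 9 = 135-configuration benchmark auditable.

### MTLR

Time is discretized on a grid $\tau_1 < \dots < \tau_m$ placed at event-
time quantiles with $m = \lceil\sqrt{\#\text{events}}\rceil$ (quantile
grids keep roughly equal information per interval; the square-root rule
balances resolution against parameters per event). A subject's outcome is
the monotone binary sequence $y_j = 1[\text{event by }\tau_j]$; the
sequence switching after position $k$ scores
$\sum_{j>k}(\theta_j \cdot x + b_j)$ and the model is the Gibbs
distribution over the $m+1$ legal sequences. Uncensored subjects
contribute the probability of the interval containing their event time;
censored subjects marginalize over all sequences with event after the
censoring time, the censoring time being mapped to the nearest lower grid
index. The objective is the summed negative log-likelihood plus
$(C/2)\lVert\Theta\rVert^2$ and a smoothness term
$\lambda_s\sum_j\lVert\theta_{j+1}-\theta_j\rVert^2$, minimized by
L-BFGS from zero initialization (deterministic) to projected-gradient
tolerance $10^{-5}$. The gradient is analytic and is verified against
finite differences in the test suite. Hyperparameter defaults offered to
the tuner: $C \in \{0.01, 0.1, 1, 10\}$, $\lambda_s \in \{0, 0.1\}$.

Because each subject has her own sequence distribution, MTLR curves may
cross, and they need not reach zero at the horizon — both properties are
asserted in the tests (the latter contrasts with discrete models that
force all mass inside the observation window).

### Soft-L1-Hinge finetuning

After likelihood pre-training, `finetune_soft_l1()` takes gradient steps
on a differentiable surrogate of the evaluation loss. The evaluation uses
the *median* of the ISD, so the default surrogate is a smoothed median:
$\hat t(x) = \sum_k \Delta\tau_k\,\sigma\{(S(\tau_k|x)-0.5)/h\}$
(trapezoid-integrated; temperature $h = 0.05$), which converges to the
evaluated median as $h \to 0$. An expected-survival-time surrogate
($\hat t = \sum_k S(\tau_k|x)\Delta\tau_k$) is also provided, but for
right-skewed distributions the mean exceeds the median, and in our
measurements minimizing it consistently *worsened* the median-based
L1-Hinge loss; the smoothed median is therefore the default. The
uncensored part of the loss is a smoothed absolute error; the censored
part is $\mathrm{softplus}(c - \hat t)$, which vanishes once the
prediction clears the censoring time. Steps are backtracked so the
surrogate never increases; divergence (loss above ten times its starting
value) aborts and returns the pre-trained parameters. Finetuning helps
most when pre-training is shrinkage-limited (large $C$), which is the
regime the tests exercise.

### Evaluation metrics

* **L1-Hinge loss** (months): $|\hat t - t|$ for uncensored subjects;
  $\max(0, c - \hat t)$ for censored ones — a prediction after the
  censoring time is not penalized. Predicted medians that never cross 0.5
  even after tail extrapolation are capped at 10 × the maximum observed
  follow-up (some cap is needed for finite means; the multiple is
  configurable).
* **Time-invariant C-index**: concordance of predicted medians over
  comparable pairs (an event strictly preceding another subject's
  observed time). Harrell conventions: tied predictions credit 0.5, pairs
  tied on event time are not comparable.
* **D-calibration**: the survival probabilities evaluated at observed
  times should be uniform; censored subjects spread their unit weight
  uniformly over $[0, S_i(c_i)]$. Pearson's statistic over $B = 10$
  equal bins is referred to $\chi^2_{B-1}$ (the goodness-of-fit
  convention for externally supplied probabilities), and a model is
  D-calibrated when $p > 0.05$. Bin edges are closed on the upper end so
  edge values resolve deterministically to the lower bin.
* **Kaplan–Meier with Greenwood bands** for cohort description, via
  `survival::survfit` with log(−log) intervals.

The Brier score is deliberately absent: under ~97% censoring its
population-weighted form carries little individual-level information.

The selection rule across configurations is: lowest mean L1-Hinge among
configurations D-calibrated in *every* fold, ties (within $10^{-9}$)
broken by mean C-index. Per-fold calibration is authoritative; a pooled
variant is easy to compute from the fold table but stricter per-fold
checking is what the rule needs.

### Curve statistics and counterfactuals

Curves interpolate linearly between grid points. The median is the first
crossing of 0.5; if a curve ends above 0.5 its final segment's slope is
extended (`linear_last_segment`) — predicted medians can legitimately
exceed the follow-up horizon, and a flat tail yields an infinite
sentinel. Attained ages round *up* (a woman recruited at 62 reaching 267
months is in her 85th year). Counterfactual edits apply to exactly one
actionable feature per call, on the raw scale, and are re-passed through
the fitted transform; editing an intrinsic feature is refused. The
reports are model counterfactuals, not causal claims: the generator's
optional health-consciousness confounder exists precisely so that
analyses can reproduce, qualitatively, how unobserved confounding can
make supplements look protective or deleterious.

## The synthetic generator

The generator emulates the cohort structure the pipeline assumes:

* n = 18,288 subjects by default, age 35–70 at recruitment;
* event times from a Weibull proportional-hazards law (shape 1.5 —
  hazard increasing with time since recruitment; the Weibull nests the
  exponential and has a closed-form survival oracle for tests);
* a sparse linear risk structure on ten features — positive
  log-hazards for age, social connection and share indices, hormone
  replacement history, whole-grain consumption and vitamin E intake,
  negative for selenium intake, orange-vegetable and fish consumption and
  menarche age — with magnitudes 0.15–0.30 per SD (hazard ratios
  ≈ 1.16–1.35 per SD, typical of lifestyle epidemiology);
* administrative censoring uniform on [95, 207] months, independent of
  features (mirroring staggered study entry without modelling entry
  dates);
* the baseline scale calibrated by bisection (tolerance 0.1 percentage
  points) so the realized event rate matches the 3.31% target;
* block-level missingness (whole questionnaires: 15% diet, 12% physical
  activity; none for baseline or HLQ, whose completion is an inclusion
  criterion) followed by 2% item-level missingness, both completely at
  random — only the two *causes* of missingness are emulated, not an
  informative mechanism;
* an optional latent health-consciousness factor loading on
  diet/supplement/activity features and (negatively) on the hazard,
  strength 0 by default.

What the generator does **not** emulate: within-block feature
correlation beyond the single confounder, informative censoring or
missingness, calendar entry dates, competing risks, and measurement
error in self-reports. Passing tests therefore demonstrate that the
pipeline recovers structure *of this kind*; they say nothing about
unmodelled features of real questionnaire data.

## Numerical choices and degenerate inputs

* Cox fits use Breslow tie handling throughout (months-resolution data
  tie heavily); RFE importance is Wald $|z|$; inestimable coefficients
  score zero and are eliminated first; singular fits are
  ridge-stabilized.
* mRMR uses the difference (relevance − redundancy) combination;
  relevance is $|C - 0.5|$ so protective and deleterious features score
  symmetrically; all greedy/elimination ties break by column order.
* Chained-equations imputation runs a fixed 10 sweeps with deterministic
  predictions (no residual draws); a seed hook exists for stochastic
  variants. Whether to pool multiple completed datasets is out of scope —
  one completed dataset per method, as the pipeline consumes.
* Imputation and encoding are fitted within each training fold and
  applied to its test fold, avoiding leakage; the test suite checks that
  apply-set permutations leave fitted transforms bit-identical.
* Fold stratification: within each censoring class, subjects are ranked
  by time, binned into quintiles (cells smaller than the fold count are
  merged), and dealt round-robin in seeded random order.
* One-hot columns are penalized independently in the elastic net (no
  group penalty); a category unseen at apply time yields all-zero
  indicators with a warning.
* Degenerate inputs fail loudly and specifically: all-missing columns,
  fewer than k donors, unreachable event-rate targets, negative times,
  zero comparable pairs, dimension mismatches.

## Problem sizes

The test suite and analysis drivers use sizes chosen to exercise each
claim at desk scale: full-size (n = 18,288) cohorts for generation-level
checks; n = 10,000 with a 10% event rate for selection recovery (ten
seeds); n = 2,000 for calibration and KM-match properties (twenty
seeds); n = 3,000 for end-to-end pipeline runs; and n ≤ 50 fixtures
wherever a brute-force oracle verifies a metric exactly.

## Known limitations

* The five adapter-slot model families are not implemented; conclusions
  about "the best of nine models" require registering real constructors.
* MICE here is single-imputation by chained equations; no Rubin pooling.
* The counterfactual reports inherit every limitation of the fitted
  model — in particular, under confounding they quantify association,
  not intervention effects.
* The generator's missingness is MCAR; imputation comparisons on it
  cannot reveal MNAR-related failure modes.
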