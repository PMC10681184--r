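---
title: "Dual proportion-congruency designs: construction, belief tracking, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual proportion-congruency designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcstroop)
```

## The experimental problem

In a spatial Stroop task an arrow appears at one of four corners and points
towards one of the same four corners; participants respond to the direction
and must ignore the position. Incongruent trials (direction != position) cost
time and accuracy — the Stroop effect. Cognitive control over this conflict
can be engaged *proactively* (sustained preparation when conflict is likely)
or *reactively* (just-in-time recruitment triggered by the stimulus). The
standard way to move each mode is to manipulate the proportion of congruent
trials (PC): list-wide (LWPC, per block) for proactive control, item-specific
(ISPC, per target location) for reactive control. `pcstroop` implements the
full computational workflow of an emotional-priming variant of this paradigm
in which both manipulations run simultaneously in every block, each trial is
preceded by a sad or neutral face prime, and the analysis is a linear mixed
model over inverse-transformed reaction times with crossed participant and
prime-image random effects.

## Block design and its confound structure

`default_block_design()` ships six blocks of 96 trials (24 per location, so
every location is equally probable). Block LWPC is .25/.50/.75 and mirrors
across blocks 1&5, 2&4 and 3&6, balancing the presentation order of low- and
high-PC blocks. Within a block, the congruent (diagonal) counts offset the
block LWPC by (+.125, +.083, −.083, −.125) per location — e.g. diagonal
(21, 20, 16, 15) in the .75 blocks — with the location assignment reversed
in the mirror blocks, so the item-specific series is not a copy of the
list-wide one.

The key confound of any PC manipulation is *contingency*: the probability of
the response given the location (PRS). A location that is 87.5% congruent is
also a location where one response is 87.5% likely, so associative learning
could mimic reactive control. Since the congruent cell's PRS mathematically
equals its ISPC, the only freedom lies in the incongruent cells. The default
design's off-diagonal counts come from a deterministic design-time
coordinate-descent that minimizes the block-level, count-weighted
correlations of PRS with both ISPC and LWPC, under two practicability caps
(no off-diagonal cell above 14 trials, no direction above 40 per block, so
the trial order remains pseudorandomizable). The residual correlation is then
driven to near zero at the *trial-wise* level by list selection (below). Any
user-supplied set of 4x4 count matrices can replace the default via
`block_design()` or a YAML file.

## Pseudorandomization

`pseudorandomize()` orders each block under the usual first-order-priming
controls: no two consecutive trials share the target location, none share the
target direction (direction determines the response key, so this also
forbids response repetitions), and congruency runs are capped at 5. The
constraints also hold across block boundaries. The sampler draws trials
weighted by remaining counts, with a one-step feasibility lookahead (a class
holding more than half the remaining trials forces alternation) and bounded
restarts; infeasible inputs — e.g. a location on more than half the trials —
are rejected up front with the violated constraint named. Everything is
deterministic given a seed; `generate_candidates()` derives distinct child
seeds from one master seed. The mid-task break is placed after
`floor(total/2)` trials.

## Trial-wise beliefs: the binary Hierarchical Gaussian Filter

Participants cannot know a block's probabilities at its first trials, so
block-wise constants are poor regressors. `trialwise_predictors()` replaces
them with the evolving beliefs of an ideal observer: a three-level binary
Hierarchical Gaussian Filter, whose level 2 tracks the logit-scale tendency
of the event and whose level 3 tracks its log-volatility, yielding
precision-weighted prediction-error updates with a dynamic learning rate (a
Bayesian analogue of Rescorla–Wagner learning). Five predictors are
computed, all as one-step-ahead predictions (the belief held *before* the
trial; a posterior-timing variant sits behind the `timing` flag):

* **LWPC** — one tracker over the congruency sequence of all trials;
* **ISPC** — one tracker per location, updated only on that location's
  trials;
* **PRS** — per location, four one-vs-rest trackers over direction identity,
  read out at the direction actually shown;
* **PR**, **PL** — one-vs-rest direction and location trackers over all
  trials (low-level confounds).

Defaults are `kappa = 1`, `omega = -2`, `mu2_0 = 0` (first prediction
exactly 0.5), `sigma2_0 = 1`, `mu3_0 = 1`, `sigma3_0 = 1`, and
`theta = exp(-6)`. The level-3 innovation variance deserves a note: large
values (order 0.1 and up) make the mean-field update's level-3 precision go
non-positive on realistic sequence lengths — a known failure mode of this
filter — so the package defaults to the conventional weakly-volatile regime,
which was uniformly stable in a 200-sequence stress scan. With `theta = 0`
and a tight level-3 prior the filter reduces to a fixed-volatility tracker.
All predictors are used on the natural-log-odds scale and are finite by
construction.

## List selection

The study's construction generates 1000 candidate lists and keeps the one
whose trial-wise ISPC and PRS series share the least variance (squared
Pearson correlation on the logit scale), with ties broken towards the lowest
candidate index. `selection_study()` reproduces this end to end and reports
the winner's three pairwise shared variances. Because the congruent-trial
ISPC and PRS values coincide identically, the *expected* correlation is
positive; the design's off-diagonal structure supplies a balancing negative
component on incongruent trials, and the minimum over 1000 random orders
lands near zero. The selected value is a realization of a minimum over
random draws, so it moves by a few tenths of a percentage point across
master seeds.

## The generative model

`simulate_dataset()` produces complete cohorts with the structure the
analysis assumes. Fixed effects on the iRT scale (iRT = −1000/RT, RT in ms)
default to the final-model estimates of the reference analysis — intercept
−2.329, Congruency 0.225, LWPC 0.058, Congruency×LWPC 0.054, and so on —
over the same coded, standardized design matrix the preprocessing stage
builds (effect codes ±1; logit-scale probabilities, trial rank and preceding
iRT standardized). Random variation follows the variance partitioning used
in the study's power analysis: of a total random-plus-residual variance
`total_var = 0.2` (iRT² units, giving a residual SD of about 0.35 and
realistic 350–550 ms mean RTs), 10% goes to participant intercepts, 10% to
image intercepts, 20% to participant congruency slopes and 60% to the
residual. Temporal dependence is generated through the preceding-iRT term
itself (coefficient 0.086 on the standardized previous simulated iRT, first
trial initialized from a marginal draw), so the autocorrelation control in
the analysis recovers a true effect. Response errors are Bernoulli with
congruent/incongruent rates .01/.03 (accuracy at ceiling on congruent
trials); RTs are clipped at 150 ms and censored at the 2000 ms timeout
(recorded as missing). Emotion is balanced 50/50 within each block ×
congruency cell (odd cells round alternately); primes are drawn uniformly
within emotion (images 1–20 sad, 21–40 neutral) with no immediate
repetition. All participants traverse the same selected list, and image
intercepts are shared across participants, as in the study. In the rare
event the linear predictor plus residual implies a non-negative iRT the
residual is resampled and the event counted.

## Preprocessing

`apply_exclusions()` removes, per participant: the first trial, the first
trial after the break, error trials (incorrect or missing responses —
timeouts count as missing), and the trial following each error. The
preceding iRT attached to each retained row is the iRT of the immediately
preceding *presented* trial, whether or not that trial survives; rows whose
predecessor has no iRT are dropped and counted. The operator is idempotent.
`build_design_matrix()` applies the coding (congruent = −1 / incongruent =
+1; neutral = −1 / sad = +1; left/lower = −1, right/upper = +1 for position
and direction — the sign convention is a documented choice, flipping only
coefficient signs) and standardizes the continuous predictors on the
analysis sample, with an option to reuse fixed constants (the
generator/analysis round trip in the test suite uses this).

## Mixed model, selection, outliers, R²

`fit_mixed_model()` estimates the Gaussian LMM with crossed participant and
image random effects by REML through lme4, with Satterthwaite degrees of
freedom via lmerTest (or a flagged normal approximation for speed on large
fits). The full model's by-participant structure carries correlated
intercepts and slopes for Congruency × LWPC × Emotion and Congruency × ISPC
× Emotion with all lower-order terms (12 terms, 78 covariance parameters);
the final structure drops every Emotion slope (6 terms, 21 parameters).
`backward_eliminate()` wraps the standard stepwise procedure (random terms
first, by pairwise likelihood-ratio tests at `alpha_random = 0.1`, then
fixed terms at `alpha_fixed = 0.05`, never orphaning a retained
interaction; the thresholds are the procedure's conventional defaults and
are configurable) and reports the full-vs-final likelihood-ratio test.
`outlier_refit()` removes trials with absolute standardized conditional
residuals above 2.5 SD and refits once, after selection, in that order;
under Gaussian residuals the expected removed fraction is 2Φ(−2.5) ≈ 1.24%.
`variance_explained()` gives the Nakagawa-style marginal and conditional R²,
with random-slope terms contributing the average row-wise quadratic form of
their covariance matrix.

## Post-hoc contrasts

`estimate_slopes()` and `marginal_means_at()` are exact linear functions of
the fixed effects with delta-method standard errors — the emmeans package
reproduces them, and the test suite uses it as an independent cross-check.
The default slope-contrast family has four members (Emotion within each
Congruency level, Congruency within each Emotion level); the family size
`k` is an explicit argument because a 2×2 grid also admits the 6-pairwise
reading. Marginal means are evaluated at the observed extremes of the
trial-wise LWPC predictor with all other continuous predictors at 0; the 8
means yield 28 pairwise contrasts. `tukey_adjust()` maps a family of k
comparisons to m means with choose(m, 2) ≥ k and uses the studentized-range
distribution; k = 1 returns the unadjusted p.

## Power analysis

`crossed_power()` implements the variance-partitioning formulation for
fully-crossed designs: under the counterbalanced design (each of the 20
actor identities contributes a sad and a neutral image, so stimulus
intercepts cancel in the condition contrast) the variance of the condition
effect is 2·V_pslope/p + 2·V_sslope/q + 4·V_resid/(pq), the noncentrality
is d over its square root, and the test is a two-tailed noncentral t with
Satterthwaite-combined degrees of freedom. A stimuli-within-condition
variant sits behind the `design` flag. `minimal_detectable_effect()` inverts
the power curve by bisection; `effect_size_convert()` implements f = d/2 and
η²p = f²/(1+f²); `rm_anova_sensitivity()` solves the within-subject
noncentral-F sensitivity problem with λ = f²·n·m/(1−ρ). The number of
repeated-measure levels m materially moves the detectable effect, so it is
an explicit argument.

## Problem sizes and reproducibility

The package-level acceptance script regenerates everything from scratch:
the analytic power value; the full 1000-candidate selection; and a
recovery study of five replicate 74-participant cohorts (about 42,600
trials each) simulated from the default generative parameters and refitted
with the final model, whose mean recovered Congruency and Congruency×LWPC
coefficients are reported with their between-replicate SEs. Five replicates
keep the recovery mean's sampling error well below the coefficients'
single-cohort standard errors while the whole study remains a desk-scale
computation. The unit-test suite runs the same machinery on a two-block
mini design (8 trials per location) and cohorts of 2–12 participants, which
exercises every code path at a fraction of the cost.

## What the synthetic data do and do not show

The generator emulates the analysis model exactly: Gaussian iRT residuals,
linear fixed effects on coded predictors, crossed Gaussian random effects,
lag-1 dependence through the preceding-iRT term, and congruency-dependent
errors. Real data differ in ways the simulation does not attempt: RT
distributions are heavier-tailed than the inverse-Gaussian-like shape
implied here (the outlier-refit stage exists for exactly that reason),
error processes depend on speed-accuracy trade-offs rather than a fixed
Bernoulli rate, learning is not stationary within blocks, and prime images
carry idiosyncratic low-level features beyond a random intercept. Passing
parameter recovery therefore validates the pipeline's correctness — coding,
exclusions, transforms, estimation — not the psychological model itself.
Known limitations: the HGF is used as a fixed-parameter ideal observer (no
per-participant fitting); the backward-elimination and outlier thresholds
follow convention rather than optimization; and the exact count matrices of
the original task are not public, so the default design reproduces its
documented structure, not its literal cells.
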