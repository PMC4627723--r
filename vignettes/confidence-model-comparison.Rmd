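---
title: "Comparing models of confidence in two-interval forced choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing models of confidence in two-interval forced choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the generative model

In a two-interval forced-choice (2IFC) contrast-discrimination task an
observer sees two brief stimulus intervals, one of which contains a target
of elevated contrast, reports which interval held the target (decision
`d`, 1 or 2), and rates confidence on a 1–6 scale. `confbms` implements a
fully Bayesian comparison of three hypotheses about how the confidence
report is computed from the sensory evidence, together with the Monte-Carlo
machinery needed to score those hypotheses on trial-level data.

The sensory front end is shared by all three hypotheses. On a trial with
target interval `i` and added contrast `s` (one of 0.015, 0.035, 0.07,
0.15 on a 0.10 baseline; the model works on the added-contrast scale), the
observer receives two independent Gaussian signals:

* `x_i ~ N(s, sigma^2 / 2)` from the target interval,
* the other signal `~ N(0, sigma^2 / 2)`,

so that the difference `x2 - x1` has variance `sigma^2`, the usual
psychophysical convention. `sigma` is the observer's sensory noise in
contrast units.

A decision variable `z_D(x)` is compared with a single threshold: interval
2 is chosen iff `z_D` strictly exceeds it (ties resolve to interval 1 — a
measure-zero event fixed for determinism). A confidence variable
`z_C(x; d)` is then compared with five ordered thresholds per decision,
with the outer bounds at plus and minus infinity, so `c` is the bin index
with `theta[d, c-1] < z_C <= theta[d, c]`.

The three candidate computations:

| model | `z_D(x)` | `z_C(x; d)` |
|---|---|---|
| difference | `x2 - x1` | `±(x2 - x1)`, signed toward the choice |
| max | `x2 - x1` | `x_d`, the signal from the chosen interval |
| bayes | `P(i = 2 \| x)` | `P(i = d \| x)`, the posterior probability the choice is correct |

The ideal-observer posterior marginalizes the unknown contrast over the
four-element contrast set with equal weights and assumes equal prior
probability of the two intervals. `bayes_posterior()` evaluates it in log
space with a max shift, so it is exact (to double precision) even for
signals far outside the plausible range.

Finally, with probability `b` (the lapse rate) a trial's decision and
confidence are replaced by a uniform draw over the 12 response cells.
Inference treats lapses analytically as a mixture —
`(1 - b) * P + b / 12` per cell — which removes Monte-Carlo variance and
keeps every cell probability strictly positive (so log-likelihoods are
finite whenever `b > 0`). The simulator instead draws discrete lapse
events; the two views are distributionally identical.

## Thresholds as response probabilities

The decision and confidence thresholds live on the scale of `z_D` and
`z_C`, which differs radically between models (a signed contrast difference
versus a probability). Priors on raw thresholds would therefore be
model-dependent and hard to justify. The package instead reparametrizes
thresholds by the 2 × 6 matrix `p` of marginal response probabilities:
`p[d, c]` is the probability, aggregated over the eight (interval,
contrast) conditions in equal proportion (the balanced design), of giving
decision `d` with confidence `c`. For a fixed model, `sigma`, and `b`, the
map between `p` and the thresholds is one-to-one, and a single flat
Dirichlet prior over `p` serves every model.

The map is inverted by sampling (`build_sample_pool()`,
`calibrate_thresholds()`): draw a pool of sensory samples (default 12 500
per condition, 10^5 pooled), compute each sample's `z_D`, and place the
decision threshold so that the target fraction `p(d = 1)` of samples falls
below it. Decisions are then assigned to every pool sample, confidence
variables are computed given those decisions, samples on the wrong side
are discarded per branch, and the five interior confidence thresholds are
placed at the conditional quantiles of the branch.

Numerical conventions, chosen once and shared bit-for-bit by the R path
and the C++ likelihood kernel:

* target counts are `round(cumulative probability × branch size)` with
  half rounded up, cumulatively, so the six bin counts sum exactly to the
  branch size and no drift accumulates across bins;
* each threshold sits at the midpoint of the two order statistics
  straddling its target count; boundary targets go strictly below the
  minimum or above the maximum sample;
* values exactly equal to a threshold fall in the lower bin, matching the
  `<=` in the confidence rule; ties between samples are broken stably;
* a decision branch whose positive target count is below `min_branch`
  (default 100) samples raises a diagnosable degenerate-branch error —
  quantiles of a near-empty branch would be meaningless. During evidence
  estimation such parameter draws are instead assigned likelihood zero.
  A branch with exactly zero target mass is simply left unreachable.

`response_cell_table()` composes the forward map: calibrate thresholds
from `p` on the pooled sample, re-bin the same draws per condition, and
apply the lapse mixture. Reusing one pool for calibration and frequency
estimation follows the procedure the estimator is built around; it can
introduce a small in-sample bias, which the default pool size makes
negligible (the round-trip error of the aggregated table is at most
`2 / N`).

## Model evidence

For one subject with trials `(i_k, s_k, d_k, c_k)` the likelihood under a
model is the product over trials of the cell probabilities
`P(d_k, c_k | i_k, s_k, m, p, sigma, b)`. The model evidence integrates
this likelihood over the priors

* `sigma ~ Gamma(shape 2, scale 0.05)` (density proportional to
  `sigma * exp(-sigma / 0.05)`, mean 0.10 contrast units),
* `log10(b) ~ Uniform(-3, -1)`,
* `p ~ Dirichlet(1)` over the 12 cells,

all computed in natural log. Two estimators are provided.

`naive_evidence()` averages the likelihood over prior draws — unbiased but
high-variance, because the likelihood is sharply peaked in parameter
space. It is the package's brute-force oracle.

`importance_evidence()` is the production estimator. The response
probabilities are drawn not from the prior but from the proposal
`Dirichlet(1 + n)`, where `n[d, c]` counts the subject's responses
irrespective of trial type — an approximation to the posterior over `p`
that ignores the condition structure. Each draw is weighted by the
likelihood times the prior-to-proposal density ratio (computed as a
log-density difference, with the normalizing constants retained so the
evidence is proper, not merely proportional); `sigma` and `b` always come
from their priors. With no data the proposal equals the prior, every
weight is one, and the evidence of an empty dataset is exactly 1.

Per-draw likelihoods need a fresh cell table at that draw's
`(sigma, b, p)`. The kernel (C++, `src/mc_likelihood.cpp`) shares one pool
of standard-normal deviates per run and rescales it by each draw's
`sigma` — common random numbers, a large variance reduction with no effect
on correctness since each draw's table remains an unbiased estimate at
that draw. Because the same pool is calibrated and re-binned, a sample's
response is a function of its rank, and the kernel partitions by rank
(`nth_element`) instead of placing explicit thresholds; a consistency test
pins the kernel to the R reference path exactly.

The estimator is repeated `n_runs` times (default 10) with independent
draws *and* independent pools, so the run-to-run spread reflects every
Monte-Carlo source; the standard error is the standard deviation of
per-run log evidences over `sqrt(n_runs)`. The point estimate pools the
kept runs by log-mean-exp — equivalent to one long run — because the
log-mean-exp estimator is biased low at small sample counts and the bias
shrinks with the pooled count, while averaging per-run logs would retain
the single-run bias. Runs in which every weight vanishes are flagged,
excluded with a warning, and an error is raised only if all runs
degenerate. The importance-weighted posterior mean of `sigma` is computed
from the same weights and reported alongside.

A caveat worth knowing: for very short datasets (tens of trials) the
counts-based proposal is only loosely matched to the integrand and the
weight distribution is heavy-tailed, so the importance estimator converges
slowly from below and its run-to-run spread understates the remaining
bias. At the design's full 480 trials the proposal is well matched. The
oracle-equivalence test runs both estimators at matched honest settings
(the brute-force arm as 10 independent runs, so its standard error also
reflects pool-level variability) and checks agreement within three
combined standard errors across seeds.

## Group-level comparison

`fixed_effects_posterior()` assumes all subjects use the same model: the
posterior is proportional to the model prior (uniform by default, over
however many models are supplied) times the exponential of the
column-summed log evidence, computed with a max shift.

`random_effects_bms()` lets each subject use their own model: population
model frequencies carry a Dirichlet prior (`alpha0 = 1`), each subject's
model is a draw from them, and the per-subject evidences are the
likelihoods. The posterior over frequencies is approximated by the
standard variational fixed point: responsibilities are softmax of log
evidence plus `digamma(alpha_k) - digamma(sum(alpha))`, and the
concentrations are updated by summed responsibilities until the largest
change falls below `1e-6` (non-convergence raises an error with
diagnostics). Exceedance probabilities — the posterior probability that a
model is the most frequent — are estimated from 10^5 Dirichlet draws,
accurate to about 0.003. A dense grid integration of the exact hierarchy
at one subject shows the variational answer is a few percent overconfident
(responsibility 0.60 where the exact value is 0.50 for a 2:1 evidence
ratio); this is a property of the approximation itself, and the test suite
asserts agreement at that level rather than pretending the fixed point is
exact. `loglik_diff_test()` wraps the classical two-sided one-sample
t-test for per-subject log-evidence differences.

## The synthetic experiment

`design_trials()` reproduces the study design: 480 trials, the four
contrasts crossed with two intervals. Balanced mode places each of the
eight conditions exactly 60 times in random order; an unbalanced i.i.d.
mode is also provided since exact balance is a design convention rather
than a physical constraint. The 16 practice trials are not simulated (they
carry no analysed data), and the six spatial target positions are
irrelevant to the two-interval abstraction. `simulate_subject()` calibrates
thresholds once from the subject's `p`, then per trial draws fresh signals,
thresholds them, and applies discrete lapse replacement.

What the generator does *not* emulate: learning or drift across trials,
reaction times, non-Gaussian sensory noise, and any mismatch between the
observer's assumed noise and the true noise (the generative and assumed
`sigma` are one parameter throughout, as a single noise symbol implies; no
mismatch knob is exposed). Passing recovery tests on this generator
therefore shows the estimator chain is self-consistent under the model
family — not that real observers satisfy the family.

## Problem sizes and reproducibility

Defaults mirror the reference analysis: 10^5 pooled calibration samples,
1000 importance samples, 10 runs. The test suite and the acceptance script
scale some studies down — calibration pools of 2500 per condition and 2
runs for the 30-subject recovery study, 20-trial subjects for the
oracle-equivalence check — sizes chosen so the full suite runs on a
laptop-class single core in minutes while leaving the checked contrasts
(recovery in at least 8 of 10 replicates, agreement within 3 combined
standard errors) far from their Monte-Carlo noise floor.

Every user-facing function takes an integer `seed`; internally a single
root seed is expanded into named substreams (per subject, per run, per
pipeline stage), so any single subject/model/run is re-executable in
isolation and `run_pipeline()` with a fixed config is bit-reproducible.
`R` integer seeds stay below 2^31.

## Known limitations

* The importance sampler's small-sample downward bias (above) matters for
  datasets far shorter than the design's 480 trials; use
  `naive_evidence()` as a cross-check there.
* Evidence values include only the model-dependent part of the likelihood
  (the stimulus sequence probabilities drop out), which is all that model
  comparison needs; absolute values are not comparable across different
  stimulus sequences.
* The variational random-effects scheme is approximate at very small
  subject counts; exceedance probabilities remain well-defined but the
  expected frequencies inherit a few percent of overconfidence.
* No reaction-time, accumulator, or family-level (protected exceedance)
  extensions are provided.
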