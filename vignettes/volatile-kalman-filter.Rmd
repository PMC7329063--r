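---
title: "Tracking volatile environments with the volatile Kalman filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking volatile environments with the volatile Kalman filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkfilter)
```

## The problem

An agent repeatedly observes noisy outcomes whose underlying mean drifts
over time, and must decide *how much* to learn from each new outcome. If
the drift rate is known and constant, the Kalman filter is the optimal
learner and its gain settles to a constant. In volatile environments the
drift rate itself changes, so uncertainty - and with it the learning rate -
should rise after surprising stretches and fall in quiet ones. This is the
statistical rationale behind classic psychological accounts (Pearce-Hall
associability) of surprise-modulated learning.

`vkfilter` implements a state-space account of this problem. The
generative model has two coupled latent chains:

* a latent mean, `x_t ~ Normal(x_{t-1}, 1 / z_{t-1})`, observed through
  Gaussian noise (`o_t ~ Normal(x_t, sigma2)`) or a Bernoulli emission
  (`o_t ~ Bernoulli(s(x_t))` with `s` the logistic sigmoid);
* a latent *precision* `z_t = z_{t-1} * eps_t` that diffuses
  multiplicatively, `eps_t = eta_t / (1 - lambda)` with
  `eta_t ~ Beta((1 - lambda) a, lambda a)`, so that `E[eps_t] = 1`,
  `0 < eps_t < (1 - lambda)^{-1}`, and the Gamma family is closed under
  the diffusion.

Multiplicative precision noise is the key modelling choice: it keeps the
process variance positive *by construction* and (in the isolated
single-chain problem) admits an exact conjugate filter, so the only
approximation needed for the full model is a structured variational
factorization across the two chains. The comparator model in this space,
the hierarchical Gaussian filter (HGF), instead places an additive
Gaussian walk on log-variance and needs an extra second-order Taylor step,
which is the source of the numerical failures counted below.

## The filter

The VKF recursion (`vkf_step()`, `run_filter("vkf", ...)`) is the Kalman
filter with the constant process variance replaced by a running volatility
estimate `v_t`, plus a second error-correcting rule for `v_t` itself:

```
k_t = (w_{t-1} + v_{t-1}) / (w_{t-1} + v_{t-1} + sigma2)
m_t = m_{t-1} + k_t (o_t - m_{t-1})
w_t = (1 - k_t) (w_{t-1} + v_{t-1})
w_{t-1,t} = (1 - k_t) w_{t-1}
v_t = v_{t-1} + lambda ((m_t - m_{t-1})^2 + w_t + w_{t-1}
                        - 2 w_{t-1,t} - v_{t-1})
```

The volatility error term is the posterior expectation of the squared
state change minus its current estimate: surprise raises `v_t`, hence the
gain, hence the learning rate - a normative Pearce-Hall loop. The
autocovariance `w_{t-1,t}` between consecutive states is what makes the
expected squared change computable. With `lambda = 0` the recursion *is*
the Kalman filter with `v = v0` (tested bit-for-bit), and the Rescorla-
Wagner rule is the constant-gain degenerate case.

### Parameters

| parameter | meaning | range | default handling |
|---|---|---|---|
| `lambda` | volatility update rate (step size of the `v` rule; also the diffusion rate of the generative precision) | `[0, 1)` | free |
| `v0` | initial volatility, outcome-units^2 | `> 0` | free; fitted with an upper bound of 10 (binary) |
| `sigma2` | observation variance (Gaussian variant), outcome-units^2 | `> 0` | free |
| `omega` | noise parameter (binary variant, inference-only) | `> 0` | free |
| `m0`, `w0` | initial mean and variance | `w0 > 0` | `m0 = 0`; `w0 = sigma2` or `omega` (scale-matched neutral start; signals stabilize within a few trials regardless) |

### Binary outcomes and the two step-size conventions

For Bernoulli outcomes the observation model is nonlinear, so the
posterior is projected back onto a Gaussian by moment matching (assumed
density filtering) with a constant posterior-variance parameter `omega`.
The mean update becomes `m_t = m_{t-1} + alpha_t (o_t - s(m_{t-1}))`.

`vkf_params()` exposes two conventions for `alpha_t`:

* `mean_step = "variance"` (default): `alpha_t = w_{t-1} + v_{t-1}`, the
  form in which the update rule is usually printed. This is the
  convention used by the single-step API, the invariants, and the
  recovery/choice-model pipeline.
* `mean_step = "sd"`: `alpha_t = sqrt(w_{t-1} + v_{t-1})`. For a
  Bernoulli observation of a wide Gaussian latent, the assumed-density
  update coefficient is `s / sqrt(1 + pi s / 8)` (with `s` the predictive
  variance), which grows like `sqrt(s)` - so the root-variance step is
  the scale that moment matching actually yields when `s` is not small.

The distinction matters in practice. At the benchmark setting
(`lambda = v0 = omega = 0.1`) the variance step is about 0.11 latent
units per unit prediction error: too small to traverse the roughly 2.8
logit units between reward probabilities 0.2 and 0.8 within a typical
block, so predictions hover near 0.5. The root-variance step (~0.33)
tracks the task sharply and is the convention under which the
particle-filter agreement figures of the benchmark suite are obtained.
Conversely, in the parameter-recovery protocol (`v0 = 5`, `omega = 1`,
self-generated outcomes) the variance step recovers the published
quantiles better; the recovery pipeline therefore keeps the default.

A related caveat: the variance step feeds `(delta m)^2` back into `v_t`
with gain `lambda`, which makes the recursion *divergent* on external
binary data once `lambda * (w + v)` is sustained above roughly 1 (the
state saturates floating range within tens of trials). The fitting
objectives handle this by penalizing each unscored trial after a
divergence (30 nats per trial), which both keeps optimizers off flat
non-finite plateaus and steers them back into the stable region.
Property tests assert the positivity/ordering invariants (`w_t > 0`,
`v_t > 0`, `0 < k_t < 1`, `0 < w_{t-1,t} < w_{t-1}`) across the stable
domain; for the Gaussian variant they hold for any valid parameters
because that recursion is a contraction.

### Derived signals

* Gaussian learning rate: the gain `k_t`. Binary learning rate:
  `alpha_t`.
* `implied_obs_learning_rate()` imputes an observation-space learning
  rate `(s(m_t) - s(m_{t-1})) / (o_t - s(m_{t-1}))`; trials with a
  numerically zero prediction error are returned as `NA`, never 0/0.
  This quantity rises after switches even with `lambda = 0`, so it is
  *not* evidence of volatility tracking - the latent-space signals are.

## Generative modules

`simulate_vkf_process()`, `simulate_hgf_process()` and
`simulate_switching_task()` produce the three kinds of ground-truth data
used throughout:

* the VKF's own two-chain process (defaults `lambda = 0.15, v0 = 1,
  sigma2 = 1` in the accuracy protocol);
* the three-level HGF cascade `x3(t) ~ N(x3(t-1), nu)`,
  `x2(t) ~ N(x2(t-1), exp(kappa x3(t) + omega))`,
  `o_t ~ N(x2(t-1), sigma2)`, sampled exactly in this form (defaults
  `nu = 0.5, kappa = 1, omega = -3, sigma2 = 1`, initial means 0 and 1);
* switching probabilistic tasks: a piecewise-constant hidden state
  (Gaussian: +/-1 observed with sd 0.1; binary: reward probability
  0.8/0.2) reversing at block boundaries. The default schedule -
  blocks of 100, 25, 25, 25, 25 trials - gives a long stable phase
  followed by a volatile phase with four reversals, the structure of the
  reversal tasks used to study volatility learning. The exact schedule
  is configurable and is stored with every generated process.

The Beta concentration `a` of the precision noise (default `a = 10`) is a
simulator parameter: the multiplicative-discount construction pins the
noise mean and support but not its concentration, and `a = 10` gives
moderately tight precision diffusion. It was fixed once, before any
benchmark was run, and the particle filters use the same value, so the
benchmarks are exact references for the simulator as configured.

`generate_synthetic_subjects()` emulates the structure of a multi-cue
probabilistic go/no-go experiment: 4 cues x 120 trials per subject, an
independent binary VKF per cue, outcomes drawn from the agent's own
one-step-ahead prediction `Bernoulli(s(m_{t-1}))` and choices from a
softmax on `m_{t-1}`. What this deliberately does *not* emulate: real
reversal schedules (outcomes are self-generated, not experimenter
controlled), stimulus-specific response biases (the generator sets them
to zero), between-cue interference, or reaction-time structure. Passing
recovery tests therefore shows that the fitting machinery is consistent
for this model class at realistic sizes - not that the model fits human
data.

## HGF comparators

`hgf2_filter()` (continuous observations, two latent levels) and
`hgf3_binary_filter()` (binary observations, three levels) implement the
standard variational HGF update scheme with the usual second-order
Taylor step at the volatility level, under the standard toolbox
conventions: initial means 0 and 1, initial variances 0.1 and 1 at
levels 2 and 3; fitted bounds `0 < nu < 1`, `0 < kappa < 1`; and the
tonic log-variance fitted as `omega = omega_f - 1` so the filter is well
defined at a raw prior mean of zero. The binary variant's latent-space
learning rate is the coefficient applied to the level-1 prediction error
(the posterior variance at level 2 after the update).

The Taylor step can produce a non-positive posterior precision at the
volatility level. This is treated as a *result state*, not an exception:
the trajectory is frozen at the failing trial, flagged, and counted by
`detect_numerical_problem()`, so failure rates are measurable. Downstream
metrics consume valid runs only. A constant-`omega` variant (fixed at -4)
can be run through the same functions but is not part of the default
model space.

## Particle-filter benchmarks

Because exact inference is intractable, accuracy is measured against
sequential Monte Carlo references:

* `rbpf_vkf()`: Rao-Blackwellized - samples precision paths from the true
  multiplicative Beta diffusion and marginalizes the mean chain with an
  exact conditional Kalman filter;
* `rbpf_hgf()`: samples the third level, Kalman-marginalizes the second,
  with the observation informing `x2(t-1)` exactly as the cascade is
  generated;
* `pf_binary()`: a bootstrap filter over both chains jointly (the sigmoid
  emission breaks the conjugacy needed for marginalization).

Design choices: systematic resampling triggered at effective sample size
below half the particle count (the standard low-variance scheme); 10000
particles for printed-quality runs, 2000-3000 for repeated-run
experiments (estimates change by less than Monte-Carlo error beyond
that, which is itself tested); particle weight degeneracy raises an
error naming the trial. The per-trial volatility estimate is the inverse
posterior-mean precision computed *before* propagating the next
multiplicative noise draw, so that it conditions on exactly the same
observations as the filter's `v_t`.

Accuracy is summarized by `relative_error()` - the ratio of median
absolute state-prediction errors (filter vs benchmark, both against the
generated ground truth) minus one - and correlations are Spearman by
default (`correlation_summary()`), averaged across runs on the Fisher-z
scale (`fisher_average()`). Filtered posterior means are scored for both
the filter and the benchmark, so the ratio is insensitive to the
alignment convention.

## Fitting machinery

All fitting happens in unconstrained raw space via `transform_params()`:
sigmoid for unit-bounded rates (`lambda`, `nu`, `kappa`), `10 * sigmoid`
for the binary `v0`, `exp` for positive parameters (`beta`, VKF `omega`),
`raw - 1` for the HGF's `omega`, identity for biases. Raw 0 therefore
corresponds to `lambda = 0.5`, `v0 = 5`, `beta = 1`, HGF `omega = -1`.

* `map_fit()`: quasi-Newton (BFGS, objective tolerance 1e-10) on the
  penalized objective with a Gaussian raw-space prior; 10 restarts by
  default (prior mean plus random perturbations), a Nelder-Mead fallback
  on optimizer error, and an honest convergence flag. Warm-started refits
  inside the hierarchical loop use a single start - restarts add nothing
  once the previous optimum is available, and the recovery protocol runs
  thousands of such refits.
* `fit_series()`: MAP fit of the binary VKF or binary HGF to an outcome
  sequence (prior mean 0, variance 15.23).
* `hierarchical_fit()`: iterated empirical Bayes for the go/no-go choice
  model. Subjects are first fitted under the fixed prior (0, 6.25); the
  group mean and variance are then re-estimated and subjects refitted
  under the group prior until the group means move by less than 1e-3
  (cap 20 iterations). The variance update adds each subject's Laplace
  posterior variance (inverse Hessian diagonal, computed on the first
  pass) to the spread of the point estimates - the EM update for a
  Gaussian random-effects model. Without that term the prior collapses
  onto the point estimates and the iteration creeps instead of
  converging. Group variances are floored at 1e-6 so identical subjects
  cannot produce an improper prior. This is a deliberately simplified
  stand-in for full hierarchical Bayesian inference over both parameters
  and model identity; per-subject Laplace evidence
  (`laplace_evidence()`) is available for descriptive model comparison,
  but responsibilities and protected exceedance probabilities are out of
  scope.
* `recovery_experiment()`: repeats generate-and-refit at the published
  design (50 subjects, 4 cues x 120 trials, group truths `lambda = 0.2,
  v0 = 5, omega = 1, beta = 1`, subject SD 0.5 in raw space) and reports
  quartiles of the group mean of per-subject natural parameters. The
  volatility pair (`lambda`, `v0`) sits on a likelihood ridge and is
  recovered with visible spread; `omega` and `beta` are tighter - the
  expected identifiability ordering for this model class.

### Response models

`go_nogo_likelihood()` implements the softmax with stimulus-specific
value-independent biases composed from emotional content, outcome
valence, and their interaction, using the four literal sign patterns
(happy-rewarding `+be+bv+bi`; angry-punishing `-be-bv+bi`;
happy-punishing `+be-bv-bi`; angry-rewarding `-be+bv+bi`). Note these
four patterns are not expressible as `be*e + bv*v + bi*e*v` for any
coding of emotion/valence (the angry-rewarding cell breaks the product
structure); the lookup is intentional. `gamble_likelihood()` implements
the play/pass softmax with expected values `p * value - (1 - p) * 10`
against 0, divided by 100 (the task's maximum trial value) before the
softmax; the hypothetical feedback shown after passing never enters the
likelihood.

### Learning-rate/volatility analyses

`lr_volatility_correlation_experiment()` quantifies the qualitative
signature that separates the two binary models: per series, the
correlation between the latent-space learning rate and the
prediction-time volatility (`alpha_t` vs `v_{t-1}` for the VKF; the
level-2 update coefficient vs `exp(kappa mu3_{t-1} + omega)` for the
HGF). Conventions, fixed here because they are not derivable from first
principles: Spearman correlation (consistent with the treatment of other
non-normal filter signals; also invariant to whether the HGF volatility
is taken as `mu3` or its exponential, which are monotonically related),
Fisher-z averaging across series, and a single prior-mean optimizer
start in fitted mode (the usual MAP protocol; multistart occasionally
finds high-`kappa` optima with the opposite correlation sign). The VKF's
correlation is essentially +1 by construction; the HGF's is negative in
the large majority of fitted and random-parameter runs because its
learning rate is additionally modulated by the sigmoid of the previous
prediction, which dips exactly when volatility peaks. The *sign* of this
contrast is robust to every convention we tried; the magnitude of the
HGF's mean correlation is not, and should be read qualitatively.

`changepoint_locked_learning_rate()` aligns any learning-rate signal to
contingency switches and contrasts the mean over the five trials before
each switch with the five trials from the switch onward; windows that
would cross the series boundary or a neighbouring switch are truncated,
not skipped. For volatility-tracking agents the post-switch mean
exceeds the pre-switch mean; with `lambda = 0` the difference vanishes.

## Problem sizes

The test suite runs the full protocols at reduced size, chosen so that
each statistic is stable to well within its assertion band: 200
repetitions x 2000 particles for the accuracy experiment, 100 fitted
series for the correlation analyses, 20 recovery repetitions, 6-12 task
draws (3000 particles) for the single-task benchmarks. The acceptance
script scales up to 250-400 repetitions, 10000-particle benchmarks, the
full 1000-sequence failure count, and 50 recovery repetitions. The
published-scale references are 1000 repetitions, 500 series and 500
recovery repetitions; all are reachable through the exported functions.

## Known limitations

* The observation noise `sigma2` is a known constant; joint tracking of
  observation noise and volatility is not attempted.
* Strictly filtering: no smoothed (backward) posteriors.
* Hierarchies deeper than the HGF's three levels, multi-cue filters with
  attention weights, and continuous-time variants are out of scope.
* The binary variance-step recursion diverges outside its stable
  parameter domain (see above); fits are protected by the graded
  penalty, but raw trajectory simulation at extreme parameters will
  saturate floating range.
* The empirical-Bayes group fit is a point-estimate approximation to a
  full random-effects treatment; its hierarchical error bars (group SDs)
  understate posterior uncertainty.
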