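---
title: "State-space modeling of mouse-tracking trajectories: model, estimation, and design choices"
author: "mtssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space modeling of mouse-tracking trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtssm)
```

## The problem

In a two-choice mouse-tracking task a participant starts each trial at a
button at the bottom-center of the screen and moves the cursor to one of
two response labels in the top corners: the correct *target* (top-right)
and the competing *distractor* (top-left). The recorded x–y cursor
stream is a continuous trace of the decision as it unfolds; curvature
toward the distractor is read as partial activation of the competing
response. Classical analyses compress each trajectory into a scalar
(maximum deviation, area under the curve, ...) and model those scalars.
`mtssm` instead models the trajectories themselves, jointly across
subjects and trials, separating *individual movement dynamics* from
*experimental manipulation effects*.

## Data reduction

Raw trajectories are made comparable in three steps (`rescale_trajectory`,
`time_normalize`, `to_angles`):

1. **Rescaling.** Each trajectory is translated so its first sample is
   the origin and scaled so the screen's horizontal half-width maps to 1
   and its vertical extent to 1: x in [-1, 1] (negative = distractor
   side), y in [0, 1].
2. **Time normalization.** Each trajectory is resampled to N + 1 = 101
   points, equally spaced along the recorded sample index (0–100% of
   the movement), by linear interpolation. This is the space
   normalization convention of standard mouse-tracking software: it
   aligns trajectories on relative movement progress, discarding
   absolute duration.
3. **Angle projection.** Each (x, y) pair is mapped to its movement
   direction by the four-quadrant inverse tangent, folded into [0, pi]
   by absolute value. Angles near pi/4 point at the target corner,
   angles near 3pi/4 at the distractor corner. The folding reflects
   small downward excursions (y < 0) into the upper half-plane — the
   left/right (distractor/target) information, which is what the
   measurement model uses, is preserved. The four-quadrant inverse
   tangent is undefined at the origin, so the start sample (and any
   exactly-zero pair) is assigned the neutral angle pi/2, equidistant
   from both labels. How y < 0 samples should fold is a genuine choice;
   we chose absolute-value folding because it keeps the angle's sign
   information about lateral attraction intact.

The model's input is the I x J x (N + 1) array of angles
(`angle_dataset`): I subjects, J trials, N + 1 time steps.

## The model

**Latent movement process.** Each subject i has one latent path shared
by all of that subject's trials, a Gaussian random walk

z_{i,0} ~ N(z0_mean, z0_var),  z_{i,n} | z_{i,n-1} ~ N(z_{i,n-1}, sigma^2).

Defaults: z0_mean = 0, z0_var = 1, sigma = 1. The transition variance is
fixed, not estimated: rescaling sigma is absorbed by the scale of z in
the logistic link, so sigma = 1 loses no flexibility. The initial-state
prior is not pinned down by the model's derivation; N(0, 1) is neutral
between the two response labels and configurable.

**Measurement.** Given the latent state, each observed angle is a draw
from a two-component von Mises mixture

y_{ijn} ~ pi_{ijn} vM(mu1, kappa1) + (1 - pi_{ijn}) vM(mu2, kappa2),

with component means fixed at the known screen positions of the labels
(defaults: mu1 = 3pi/4 distractor, mu2 = pi/4 target, the corner
directions after rescaling) and concentrations kappa1, kappa2 estimated.

**Attraction probability and the stimuli equation.** The mixing
probability — the probability that a movement angle is generated from
the distractor-side component — is a logistic function of the latent
state plus a trial-level linear predictor:

pi_{ijn} = logistic(beta_j + z_{i,n}),
beta_j = sum_k d_jk gamma_k + x_j (eta + sum_k d_jk delta_k).

`D = (d_jk)` is the Boolean partition matrix of a K-level categorical
factor, x a continuous covariate, and gamma / eta / delta the
categorical, covariate, and interaction coefficients (delta_1 = 0 for
identifiability). The three presets (`model_preset`) activate the
categorical term only, the covariate term only, or all terms.

**Sign convention.** Under the literal link above, pi increases with
beta + z. Published probability graphs for this model family are drawn
with the opposite orientation (positive latent states = low distractor
activation); `sign_convention = "reversed"` reproduces that orientation
by negating the argument of the logistic. The package default is the
literal form; every function that evaluates the link takes the
convention from `model_params`, so the two stay consistent end to end.

**State-prior counting.** The complete-data factorization formally sums
the latent-path prior over trials, although the path is shared within
subject. `complete_data_loglik` counts the state terms once per subject
by default (the generative reading); `state_prior = "per_trial"`
restores the literal J-fold counting for comparison.

## Likelihood: the recursive filter

The marginal likelihood f(Y | theta) integrates the latent paths out.
Because the state is one-dimensional, this can be done essentially
exactly by a recursive filter (`ga_filter`) that carries the filtering
density forward as a compressed set of point masses:

* **Predict** is exact: the random-walk transition is a Gaussian
  convolution of the stored point masses, evaluated in closed form.
* **Update** multiplies in the pooled observation likelihood of all J
  trials at that step and renormalizes by adaptive trapezoidal
  quadrature. The base grid spans 8.5 predictive standard deviations at
  a spacing capped at 0.8 sigma (the trapezoidal Gaussian-convolution
  aliasing error is ~exp(-2 pi^2 (sigma/h)^2), i.e. below 1e-13 at that
  cap); windows around posterior peaks are refined locally (up to 3
  passes) so updates much narrower than the predictive scale stay
  resolved, and the grid extends itself when mass approaches a
  boundary. Steps whose observations carry no information about z
  (identical component densities) short-circuit to the exact analytic
  recursion.
* **Likelihood increments** are the quadrature normalizing constants;
  per-step Gaussian summaries (posterior mean and variance) feed the
  fixed-interval smoother (`ga_smoother`, a standard backward
  Rauch–Tung–Striebel pass on the random walk) and the latent-path
  estimates.

We considered the classical single-Gaussian alternatives for the update
— matching the posterior mode and curvature (Laplace) or the posterior
moments (assumed-density filtering). Both leave systematic biases of
the order of 0.1–1 nats on realistic instances because the step
posteriors are skewed and occasionally bimodal, and that bias varies
with theta, which distorts the sampler's target. The adaptive
quadrature filter removes the approximation (agreement with a dense
fixed-grid filter to ~1e-3 nats at default resolution, ~1e-5 at high
resolution) at comparable cost. An independent check is built in:
`particle_loglik`, a bootstrap particle filter with systematic
resampling, is an unbiased estimator of the same quantity, and the test
suite verifies agreement on randomized instances.

Filter resolution is set by `n_quad` (base grid points per update,
default 51), `n_refine` (points per refinement window, default 25) and
`max_refine` (passes, default 3). Refinement fires only when the local
spacing exceeds the estimated posterior scale — one point per posterior
standard deviation already gives ~1e-9 trapezoid accuracy — so these
defaults reach ~1e-4-nat agreement with a dense-grid oracle at the cost
the sampler's many likelihood evaluations can afford.

## Posterior sampling

`run_mh` samples the working-scale parameter vector — gamma, eta,
delta_2..K, log kappa1, log kappa2 — by adaptive random-walk
Metropolis–Hastings with the filter-based marginal likelihood inside
the acceptance ratio. Priors are independent N(0, 25) on every
working-scale coordinate; kappa is sampled on the log scale so the
positivity constraint is built into the parameterization and the wide
prior covers the plausible concentration range.

* **Starting values** maximize the *static* mixture likelihood (latent
  state fixed at 0), with five jittered optimization starts.
* **Starting proposal covariance** is the regularized inverse negative
  Hessian of that static likelihood. One correction is needed: the
  static likelihood conditions on z = 0 and therefore assigns no
  variance to the direction in which a constant shift of all gamma
  trades against shifting every latent path — a trade whose only cost
  is the initial-state prior, with marginal variance about z0_var / I.
  That term is added to the gamma block; without it the direction mixes
  pathologically slowly once adaptation stops.
* **Proposals** are Gaussian random walks with covariance
  s_t (2.38^2 / d) Sigma_t; Sigma_t is re-estimated from the chain
  history every `adapt_interval` (default 25) iterations *during
  burn-in only*, and the global factor s_t is nudged toward a 25%
  acceptance rate over the same windows (the Hessian-based starting
  covariance systematically understates the marginal posterior scale,
  because the static likelihood conditions on z = 0 where the logistic
  is most informative). Freezing both after burn-in keeps the kept
  draws targeting a fixed kernel, preserving standard ergodicity
  guarantees; whether to continue adapting after burn-in is a genuinely
  open choice for this sampler family, and we freeze, as we use the
  standard 2.38^2/d scaling.
* A filter failure at a proposal (an error, not just a poor value)
  rejects that proposal with a warning instead of killing the chain.
* Full-scale defaults are 20 chains x 10,000 iterations with burn-in
  2,500; all examples and tests scale these down.

Diagnostics: `gelman_rubin` computes the classic between/within-chain
potential scale reduction factor (identical constant chains report 1 by
convention) and an autocorrelation-based effective sample size.
`posterior_summary` reports the mean and the asymmetric (q0.05, q0.975)
interval per parameter — note that interval spans 92.5% probability; it
is reproduced in that form because it is the reporting layout used for
this model family — with kappa back-transformed to its natural scale.
Latent-path point estimates are posterior means of smoothed paths over
kept draws thinned by `thin_latent` (default 10); the estimator is not
prescribed by the model's derivation, so the posterior mean was chosen.

## Model evaluation

**Posterior predictive fit.** `posterior_predictive_fit` draws M
parameter vectors from the kept draws, simulates a replicate dataset
for each, and scores agreement with a bounded histogram-overlap index:
100 x (1 - total variation distance) between normalized 36-bin angle
histograms on [0, pi], pooled over all cells (overall) or per subject
(by-subject, then averaged). Fit measures for this kind of
simulation-based check are not standardized; this bounded
histogram-overlap index is our concrete choice and is labeled as such
in reports. Two replicate designs are available:

* `latent = "posterior"` (default): each subject's replicate path is
  drawn from that subject's smoothed latent posterior (computed at a
  thinned subset of parameter draws, sampling the per-step marginals).
  This is the joint posterior predictive and the right reference for
  *subject-level* checks: it asks whether the fitted model regenerates
  each observed subject.
* `latent = "prior"`: replicate paths are fresh draws of the AR(1)
  prior. This scores how well the *marginal* model reproduces a new,
  unseen subject. Because the random walk is nonstationary, a single
  realized path's angle distribution differs substantially from the
  path-averaged marginal, so by-subject indices under this design
  plateau around 65–75% even at the true parameters; overall (pooled)
  indices are barely affected. Use it for population-level claims, not
  subject-level fit.

**Attraction curves and windowed statistics.** `attraction_curves`
evaluates the logistic link at posterior-mean coefficients per factor
level (and at the lowest/median/highest covariate values when active);
`window_statistic` averages an attraction curve over a stated window of
normalized process time (e.g. 30–50%), the windowed attraction
probability p_delta.

**Profile clustering.** `cluster_profiles` groups subjects by Ward
agglomerative clustering on the Euclidean distance between their
(optionally 5-point moving-average smoothed) latent path estimates;
`k = "auto"` picks 2..min(8, I-1) by maximum mean silhouette width.
Functional-data practice offers many clustering recipes; Ward +
silhouette is our concrete choice. All-identical paths degenerate to a
single cluster with a warning.

## The synthetic-data generator

The study this model family was developed on (a lexical decision task)
is not publicly available, so `default_scenario` emulates a study of
its shape: 22 subjects, 72 trials balanced over a 3-level stimulus-type
factor (24 per level), a standard-normal per-trial covariate standing
in for a psycholinguistic predictor such as bigram frequency, and
N + 1 = 102 angle samples per trial. True coefficients
(gamma = (0.34, 1.30, 1.31), eta = 0.40, delta = (0, -0.39, -0.34)) and
concentrations (20, 45) are of the magnitude reported for that family
of analyses; component means follow the screen-corner geometry. Angles
are simulated by exactly the generative model (envelope-rejection von
Mises draws, folded into [0, pi] just as preprocessing folds real
data), so simulator and likelihood are consistent by construction.

One subtlety is worth stating precisely. The measurement density is a
mixture on the *circle*, while folded data live on \[0, pi\]; the
density of a folded draw is really f(y) + f(-y). At the
concentrations of interest (kappa of order 20–45 with means at the
screen corners) the f(-y) term is vanishingly small and the circular
likelihood is an excellent model of folded data, which is why the
folded generator is the right emulation of an experiment. For
*calibration* checks, however, generator and likelihood must agree
exactly, and the wide prior on log kappa visits near-zero
concentrations where folding matters; `simulate_angles(fold = FALSE)`
therefore draws from the model's own circular distribution, and the
calibration tests use it.

What the generator does *not* emulate: autocorrelated measurement
noise, trial-to-trial learning or fatigue, velocity/acceleration
structure, device-specific sampling artifacts, and missing samples.
Passing tests therefore certify the estimation machinery under the
model's own assumptions — not that real cursor data satisfy those
assumptions.

## Problem sizes used in tests

The test suite exercises the full pipeline at deliberately scaled-down
sizes chosen to probe each property with useful power: filter-vs-oracle
comparisons on 2 subjects x 4 trials x 51 steps (100,000 particles);
parameter recovery on 10 subjects x 36 trials x 101 steps with 4 chains
x 2,000 iterations (burn-in 500); prior-predictive calibration over 20
replications at 5 x 12 x 51 with 2 chains x 500; prior recovery with
concentrations fixed at 1e-3 on 2 x 6 x 25 with 4 chains x 4,600
(4,000 thinned kept draws). These are the package's standard
desk-scale verification settings.

## Known limitations

* One latent dimension per subject; velocity/acceleration states and
  multivariate extensions are out of scope.
* The logistic link is intercept-only in the design: manipulations
  shift the attraction probability but cannot change the latent
  dynamics themselves.
* Single categorical factor plus one covariate; no multi-factor designs
  or random slopes.
* The smoother returns Gaussian summaries of a generally non-Gaussian
  posterior; credible bands on latent paths are approximate even though
  the likelihood itself is computed to quadrature accuracy.
* Metropolis–Hastings with a full-covariance random walk mixes slowly
  past ~15 parameters; K much larger than 5 would warrant a different
  sampler.
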