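# mtssm — state-space modeling of mouse-tracking trajectories

`mtssm` analyzes computer mouse-tracking experiments — two-choice tasks
in which a participant moves the cursor from a start button to either a
*target* label (top-right) or a competing *distractor* label (top-left)
while the x–y path is recorded. Instead of compressing each trajectory
into a summary scalar, the package models the trajectories themselves
with a non-linear state-space model, separating individual movement
dynamics from experimental-design effects. It is written for cognitive
and psycholinguistic researchers who run mouse-tracking studies and for
methodologists working on dynamic models of behavioral time series.

## The model

Trajectories are reduced to movement-angle series y_{ij,0:N} in
[0, pi] (target corner at pi/4, distractor corner at 3pi/4). The model
couples:

* a **latent AR(1) movement process** per subject,
  z_{i,n} = z_{i,n-1} + sigma eps_{i,n}, shared by all of a subject's
  trials;
* a **two-component von Mises mixture measurement model**,
  y_{ijn} ~ pi_{ijn} vM(mu1, kappa1) + (1 - pi_{ijn}) vM(mu2, kappa2),
  with component means fixed at the known label directions;
* a **logistic attraction probability**
  pi_{ijn} = logistic(beta_j + z_{i,n}), where the *stimuli equation*
  beta_j = sum_k d_jk gamma_k + x_j (eta + sum_k d_jk delta_k) encodes
  a K-level experimental factor, a continuous covariate, and their
  interaction (delta_1 = 0).

Estimation is Bayesian: a recursive filter computes the marginal
likelihood of each subject's angle series by adaptive sequential
quadrature (the latent state is scalar, so the integration is
essentially exact), and an adaptive marginal Metropolis–Hastings
sampler draws gamma, eta, delta, and log kappa1/kappa2 under N(0, 25)
priors. A bootstrap particle filter is included as an independent
likelihood oracle. Model evaluation covers simulation-based posterior
predictive checks (0–100% histogram-overlap fit indices, overall and
by subject), attraction-probability curves per condition, windowed
attraction statistics (p_delta), and Ward clustering of latent
movement profiles.

## Worked example

Simulate a small study (6 subjects, 12 trials in 3 balanced levels with
a covariate, 41 time steps), fit the full-interaction model with a
scaled-down sampler, and evaluate it:

```r
library(mtssm)

sc  <- default_scenario(I = 6, J = 12, N = 41, seed = 3)
sim <- simulate_dataset(sc)
sim$Y
#> Angle dataset: 6 subjects x 12 trials x 42 time steps
#>   angle range: [ 0.374 , 3.133 ] rad

cfg <- inference_config(n_chains = 2, n_iter = 600, burn_in = 200, seed = 1)
fit <- run_mh(sim$Y, sim$design, cfg)
posterior_summary(fit)
#>   parameter        q0.05       mean      q0.975      rhat
#> 1    gamma1  1.789327970  2.3775847  3.03449026 1.0200992
#> 2    gamma2  2.219136485  2.9586317  3.83891634 1.0152406
#> 3    gamma3  2.125105490  2.8140594  3.62568796 1.0316473
#> 4       eta  0.003874971  0.4919099  1.04093832 1.0498424
#> 5    delta2 -1.182470434 -0.7263107  0.01312719 1.0908110
#> 6    delta3 -1.022254801 -0.6559944 -0.07449106 1.0003592
#> 7    kappa1 18.572836224 19.3324393 20.29719574 1.0688669
#> 8    kappa2 43.131422319 46.3591920 49.46840027 0.9991195

ppc <- posterior_predictive_fit(fit, sim$Y, M = 500, seed = 2)
ppc
#> Posterior predictive fit (histogram-overlap index, M = 500 replicates)
#>   overall fit    : 97.2%
#>   by-subject fit : 93.6% (mean over 6 subjects)
```

The summary rows are the stimuli-equation coefficients on their natural
scales: `gamma` shifts the distractor-attraction probability per factor
level, `eta` is the covariate slope, `delta` the interaction contrasts
(level 1 fixed at 0), and `kappa1`/`kappa2` are the angular
concentrations around the distractor and target directions. Intervals
are the asymmetric (q0.05, q0.975) reporting layout; `rhat` near 1
indicates converged chains. At this toy size the gamma levels absorb
part of the subjects' shared latent offset (their posterior widens and
re-centers accordingly — with more subjects the offset averages out),
while the concentrations are recovered sharply. The fit report says the
fitted model regenerates the observed angle distributions to ~97%
overlap overall and ~94% per subject. Latent movement profiles are in
`fit$latent_summaries` (one smoothed path per subject), ready for
`cluster_profiles()` and `attraction_curves()`.

Real data enter through `read_trajectories()` (CSV of
`subject,trial,sample,x,y` plus a `screen_geometry()`) and
`read_design()` (CSV of `trial,level[,x]`), or via `run_pipeline()`
with a YAML configuration; `inst/cli/mtssm.R` is a thin command-line
wrapper around the same functions.

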