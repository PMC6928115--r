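#' Simulation scenario
#'
#' Bundles the dimensions, true parameters, design and seed used to
#' generate synthetic datasets with the model's exact statistical
#' structure (latent AR(1) paths observed through the logistic-mixed von
#' Mises mixture).
#'
#' @param I,J,K,N subjects, trials, factor levels, time steps (the angle
#'   series has N + 1 samples).
#' @param theta a [model_params()] holding the true parameter values.
#' @param design a [design_spec()] with J trials and K levels.
#' @param seed integer base seed.
#' @return An object of class `sim_scenario`.
#' @export
simulation_scenario <- function(I, J, K, N, theta, design, seed = 1L) {
  stopifnot(I >= 1, J >= 1, K >= 1, N >= 1)
  if (design$J != J || design$K != K)
    stop("design dimensions disagree with the scenario")
  structure(list(I = I, J = J, K = K, N = N, theta = theta,
                 design = design, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Default synthetic scenario
#'
#' A stand-in for a typical mouse-tracking lexical decision study: 22
#' subjects, 72 trials balanced over a 3-level stimulus-type factor (24
#' trials per level) with a standard-normal per-trial covariate, angle
#' series of 101 steps. Component mean directions follow the screen-corner
#' geometry (3*pi/4 distractor, pi/4 target); concentrations (20, 45) and
#' stimuli coefficients gamma = (0.34, 1.30, 1.31), eta = 0.40,
#' delta = (0, -0.39, -0.34) are of the magnitude typically estimated in
#' such experiments. All terms of the stimuli equation are active.
#'
#' @param I,J,N optionally scaled-down dimensions; J must be a multiple
#'   of 3 (levels stay balanced).
#' @param seed integer seed controlling the covariate draw and, by
#'   default, downstream simulation.
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(I = 22, J = 72, N = 101, seed = 101L) {
  if (J %% 3 != 0) stop("J must be a multiple of 3 to keep levels balanced")
  set.seed(seed)
  level <- rep(c("HF", "LF", "NW"), each = J / 3)
  x <- rnorm(J)
  design <- design_spec(level, x = x,
                        active = c("categorical", "covariate",
                                   "interaction"))
  theta <- model_params(gamma = c(0.34, 1.30, 1.31),
                        delta = c(0, -0.39, -0.34), eta = 0.40,
                        kappa1 = 20, kappa2 = 45)
  simulation_scenario(I, J, 3, N, theta, design, seed = seed)
}

#' Simulate latent AR(1) movement paths
#'
#' Draws z_(i,0) from the initial-state prior and propagates the Gaussian
#' random walk z_(i,n) = z_(i,n-1) + sigma * eps.
#'
#' @param scenario a `sim_scenario`.
#' @param seed optional seed; defaults to `scenario$seed + 1` so the data
#'   stream is distinct from the covariate draw in the design.
#' @return Numeric I x (N + 1) matrix of latent paths.
#' @export
simulate_latent <- function(scenario, seed = scenario$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  th <- scenario$theta
  n1 <- scenario$N + 1
  Z <- matrix(0, scenario$I, n1)
  Z[, 1] <- rnorm(scenario$I, th$z0_mean, sqrt(th$z0_var))
  if (n1 > 1) {
    steps <- matrix(rnorm(scenario$I * (n1 - 1), 0, th$sigma),
                    scenario$I, n1 - 1)
    Z[, -1] <- Z[, 1] + t(apply(steps, 1, cumsum))
  }
  Z
}

#' Simulate observed angles given latent paths
#'
#' For each (subject, trial, step): compute the attraction probability
#' from the stimuli equation and the latent state, pick the
#' distractor-side von Mises component with that probability (the
#' target-side component otherwise), draw the angle by envelope
#' rejection, and fold it into \[0, pi\] by absolute value — the same
#' folding the preprocessing applies to observed data.
#'
#' @param Z numeric I x (N + 1) latent paths from [simulate_latent()].
#' @param scenario a `sim_scenario`.
#' @param seed optional seed (set it only when calling this step on its
#'   own; [simulate_dataset()] manages seeding across both stages).
#' @param fold fold draws into \[0, pi\] (default), matching what
#'   preprocessing does to experimental data. `fold = FALSE` returns the
#'   raw circle-valued draws in (-pi, pi\] as a plain array — the
#'   measurement model's own distribution, used for self-consistency
#'   (calibration) checks where generator and likelihood must agree
#'   exactly.
#' @return An [angle_dataset()], or a plain I x J x (N + 1) array when
#'   `fold = FALSE`.
#' @export
simulate_angles <- function(Z, scenario, seed = NULL, fold = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  th <- scenario$theta
  beta <- stimuli_equation(scenario$design, th)
  arr <- simulate_angles_cpp(as.matrix(Z), beta, th$mu1, th$mu2,
                             th$kappa1, th$kappa2,
                             sign_mult(th$sign_convention), fold)
  if (fold) angle_dataset(arr) else arr
}

#' Simulate a complete dataset
#'
#' Runs [simulate_latent()] then [simulate_angles()] under a single seed.
#'
#' @param scenario a `sim_scenario`.
#' @param seed optional seed; defaults to `scenario$seed + 1` (one stream
#'   for latent paths and angles, distinct from the design's covariate
#'   draw).
#' @return A list with `Y` (an [angle_dataset()]), `Z` (latent paths),
#'   `design`, and `theta` (true parameters).
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed + 1L) {
  if (!is.null(seed)) set.seed(seed)
  Z <- simulate_latent(scenario, seed = NULL)
  Y <- simulate_angles(Z, scenario, seed = NULL)
  list(Y = Y, Z = Z, design = scenario$design, theta = scenario$theta)
}

#' Draw from the von Mises distribution
#'
#' Envelope-rejection sampler (Best-Fisher); angles returned in
#' (-pi, pi\].
#'
#' @param n number of draws.
#' @param mu mean direction.
#' @param kappa non-negative concentration; 0 gives the uniform circle.
#' @return Numeric vector of angles.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be non-negative")
  rvonmises_cpp(as.integer(n), mu, kappa)
}
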