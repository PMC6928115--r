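# Shared fixtures. Heavyweight fits are memoized so several tests can
# reuse one sampler run.

.fixture_env <- new.env(parent = emptyenv())

# two-level categorical scenario, small enough for oracle comparisons
small_scenario <- function(N = 50, seed = 7) {
  p <- model_params(gamma = c(0.5, 1.2), delta = c(0, 0), eta = 0,
                    kappa1 = 20, kappa2 = 45)
  des <- design_spec(rep(c("a", "b"), 2), active = "categorical")
  simulation_scenario(2, 4, 2, N, p, des, seed = seed)
}

# scaled-down parameter-recovery fit (10 subjects, 36 trials, 101 steps;
# 4 chains x 2000 iterations, burn-in 500), shared by the recovery and
# posterior-predictive tests
recovery_fit <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  sc <- default_scenario(I = 10, J = 36, N = 101, seed = 42)
  sim <- simulate_dataset(sc)
  cfg <- inference_config(n_chains = 4, n_iter = 2000, burn_in = 500,
                          seed = 7)
  fit <- suppressWarnings(run_mh(sim$Y, sim$design, cfg))
  .fixture_env$recovery <- list(scenario = sc, sim = sim, fit = fit)
  .fixture_env$recovery
}

# build an mh_draws object directly from a draw matrix (chains x kept x d),
# for diagnostics/summary tests that do not need a real sampler run
fake_draws <- function(draws, param_names,
                       design = design_spec(c("a", "b", "c"),
                                            active = "categorical"),
                       base = NULL, fix_kappa = NULL) {
  if (is.null(base))
    base <- model_params(gamma = rep(0, design$K),
                         delta = rep(0, design$K))
  structure(list(draws = draws, param_names = param_names,
                 acceptance_rate = rep(0.3, dim(draws)[1]),
                 config = inference_config(n_chains = dim(draws)[1],
                                           n_iter = dim(draws)[2] + 10,
                                           burn_in = 10),
                 design = design, base = base, fix_kappa = fix_kappa,
                 latent_summaries = NULL),
            class = "mh_draws")
}
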