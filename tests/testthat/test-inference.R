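test_that("static-likelihood initialization recovers sensible starts", {
  # data from a single target-side von Mises: mixing weight near 0
  des <- design_spec(rep("a", 6), active = "categorical")
  set.seed(21)
  Y <- angle_dataset(array(abs(rvonmises(3 * 6 * 40, pi / 4, 30)),
                           dim = c(3, 6, 40)))
  ip <- initialize_params(Y, des, seed = 1)
  expect_lt(plogis(ip$params$gamma[1]), 0.1)
  expect_gt(ip$params$kappa2, 15)
  # symmetric data split between the two components: beta near 0
  set.seed(22)
  half <- abs(c(rvonmises(1800, pi / 4, 25), rvonmises(1800, 3 * pi / 4, 25)))
  Ys <- angle_dataset(array(sample(half), dim = c(3, 6, 200)))
  ips <- initialize_params(Ys, des, seed = 1)
  expect_lt(abs(ips$params$gamma[1]), 0.15)
  # deterministic under a fixed seed
  expect_identical(initialize_params(Y, des, seed = 1)$theta, ip$theta)
})

test_that("proposal covariance inverts curvature with regularization", {
  # analytic quadratic: f(x) = -x' A x / 2 has negative Hessian A
  A <- matrix(c(3, 1, 0.5, 1, 2.5, 0.2, 0.5, 0.2, 1.8), 3, 3)
  f <- function(x) -0.5 * drop(t(x) %*% A %*% x)
  S <- mtssm:::neg_hessian_inverse(f, c(0.2, -0.1, 0.4))
  expect_equal(S, solve(A), tolerance = 1e-6)
  expect_equal(S, t(S), tolerance = 1e-12)
  # exactly singular curvature still yields a positive-definite matrix
  S0 <- mtssm:::neg_hessian_inverse(function(x) sum(0 * x), c(0, 0))
  expect_true(all(eigen(S0, symmetric = TRUE)$values > 0))
  # the real interface is symmetric and positive definite
  sc <- small_scenario(N = 15)
  sim <- simulate_dataset(sc)
  ip <- initialize_params(sim$Y, sc$design, seed = 2)
  S1 <- initial_proposal_cov(ip$theta, sim$Y, sc$design)
  expect_equal(S1, t(S1), tolerance = 1e-10)
  expect_true(all(eigen(S1, symmetric = TRUE)$values > 0))
})

test_that("the sampler is reproducible and respects fixed concentrations", {
  sc <- small_scenario(N = 15)
  sim <- simulate_dataset(sc)
  cfg <- inference_config(n_chains = 2, n_iter = 80, burn_in = 30,
                          seed = 13)
  f1 <- suppressWarnings(run_mh(sim$Y, sim$design, cfg, latent = FALSE))
  f2 <- suppressWarnings(run_mh(sim$Y, sim$design, cfg, latent = FALSE))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$acceptance_rate >= 0 & f1$acceptance_rate <= 1))
  expect_equal(f1$param_names,
               c("gamma1", "gamma2", "log_kappa1", "log_kappa2"))
  fk <- suppressWarnings(run_mh(sim$Y, sim$design, cfg,
                                fix_kappa = c(20, 45), latent = FALSE))
  expect_equal(fk$param_names, c("gamma1", "gamma2"))
  # latent summaries have one smoothed path per subject
  f3 <- suppressWarnings(run_mh(sim$Y, sim$design, cfg))
  expect_equal(dim(f3$latent_summaries), c(2, 16))
  expect_true(all(is.finite(f3$latent_summaries)))
})

test_that("Gelman-Rubin behaves at its analytic anchors", {
  const <- fake_draws(array(2.5, dim = c(3, 200, 1)), "gamma1")
  d0 <- gelman_rubin(const)
  expect_equal(d0$rhat, 1)
  set.seed(31)
  stat <- fake_draws(array(rnorm(4 * 5000 * 2), dim = c(4, 5000, 2)),
                     c("gamma1", "gamma2"))
  ds <- gelman_rubin(stat)
  expect_true(all(ds$rhat < 1.02))
  expect_true(all(ds$ess > 1000))
  off <- stat
  off$draws[1, , 1] <- off$draws[1, , 1] + 10
  expect_gt(gelman_rubin(off)$rhat[1], 1.5)
  one <- fake_draws(array(rnorm(300), dim = c(1, 300, 1)), "gamma1")
  expect_error(gelman_rubin(one), "split")
  # agreement with an established implementation on stationary chains
  skip_if_not_installed("coda")
  cl <- coda::mcmc.list(lapply(1:4, function(c_)
    coda::mcmc(stat$draws[c_, , 1])))
  expect_equal(ds$rhat[1],
               unname(coda::gelman.diag(cl)$psrf[1, 1]),
               tolerance = 0.01)
})

test_that("posterior summaries report the documented quantities", {
  x <- c(rep(3.2, 500))
  cs <- fake_draws(array(x, dim = c(2, 250, 1)), "eta",
                   design = design_spec(letters[1:3], x = rnorm(3),
                                        active = "covariate"))
  s <- posterior_summary(cs)
  expect_equal(s$q0.05, 3.2)
  expect_equal(s$mean, 3.2)
  expect_equal(s$q0.975, 3.2)
  set.seed(41)
  u <- fake_draws(array(runif(1e5), dim = c(2, 5e4, 1)), "gamma1")
  su <- posterior_summary(u)
  expect_equal(su$q0.05, 0.05, tolerance = 0.01)
  expect_equal(su$q0.975, 0.975, tolerance = 0.01)
  expect_equal(su$mean, 0.5, tolerance = 0.01)
  # kappa is reported on the natural scale
  k <- fake_draws(array(log(c(20, 45)), dim = c(2, 300, 2))[
    , , , drop = FALSE], c("log_kappa1", "log_kappa2"))
  k$draws <- array(rep(log(c(20, 45)), each = 600), dim = c(2, 300, 2))
  sk <- posterior_summary(k)
  expect_equal(sk$parameter, c("kappa1", "kappa2"))
  expect_equal(sk$mean, c(20, 45), tolerance = 1e-10)
})
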