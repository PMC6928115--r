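test_that("the histogram-overlap index hits its bounds", {
  set.seed(51)
  a <- runif(2000, 0, pi)
  expect_equal(histogram_overlap(a, a), 100)
  expect_equal(histogram_overlap(rep(0.01, 500), rep(3.1, 500)), 0)
  b <- runif(2000, 0, pi)
  h <- histogram_overlap(a, b)
  expect_true(h > 80 && h < 100)  # same distribution, sampling noise
})

test_that("posterior predictive fit scores well-specified draws highly", {
  # draws concentrated at the true parameters: the check reduces to
  # comparing two samples from the same generative model
  sc <- default_scenario(I = 6, J = 12, N = 41, seed = 61)
  sim <- simulate_dataset(sc)
  th <- c(sc$theta$gamma, sc$theta$eta, sc$theta$delta[2:3],
          log(sc$theta$kappa1), log(sc$theta$kappa2))
  dr <- fake_draws(array(rep(th, each = 2 * 100), dim = c(2, 100, 8)),
                   c("gamma1", "gamma2", "gamma3", "eta", "delta2",
                     "delta3", "log_kappa1", "log_kappa2"),
                   design = sim$design)
  rep1 <- posterior_predictive_fit(dr, sim$Y, M = 150, seed = 3)
  expect_gt(rep1$overall_fit, 85)
  expect_gt(rep1$by_subject_mean, 80)
  expect_true(all(rep1$by_subject_fit >= 0 & rep1$by_subject_fit <= 100))
  # prior-path replicates score a new subject, not the observed ones:
  # the subject-level index drops while the pooled index stays high
  repp <- posterior_predictive_fit(dr, sim$Y, M = 150, seed = 3,
                                   latent = "prior")
  expect_gt(repp$overall_fit, 80)
  expect_lt(repp$by_subject_mean, rep1$by_subject_mean)
  # histograms pool over trials, so permuting the observed trials (same
  # design, same replicate stream) changes nothing
  perm <- sample(12)
  Yp <- angle_dataset(unclass(sim$Y)[, perm, , drop = FALSE])
  rep2 <- posterior_predictive_fit(dr, Yp, M = 150, seed = 3)
  expect_equal(rep2$overall_fit, rep1$overall_fit, tolerance = 1e-10)
  expect_equal(rep2$by_subject_fit, rep1$by_subject_fit,
               tolerance = 1e-10)
  # fit degrades as the fitted concentrations drift from the truth
  fits <- vapply(c(1, 3, 9), function(f) {
    d2 <- dr
    d2$draws[, , 7] <- log(sc$theta$kappa1 * f)
    d2$draws[, , 8] <- log(sc$theta$kappa2 * f)
    posterior_predictive_fit(d2, sim$Y, M = 100, seed = 4)$overall_fit
  }, numeric(1))
  expect_true(all(diff(fits) < 0))
  expect_error(posterior_predictive_fit(dr, sim$Y, M = 10), "100")
})

test_that("attraction curves track the posterior-mean coefficients", {
  des <- design_spec(rep(c("a", "b", "c"), 4), active = "categorical")
  th <- c(0.8, 0.8, 0.8, log(20), log(45))
  dr <- fake_draws(array(rep(th, each = 200), dim = c(2, 100, 5)),
                   c("gamma1", "gamma2", "gamma3", "log_kappa1",
                     "log_kappa2"), design = des)
  cur <- attraction_curves(dr, z_grid = seq(-4, 4, 0.5))
  # identical coefficients give identical curves for every level
  sp <- split(cur$pi, cur$level)
  expect_equal(sp$a, sp$b)
  expect_equal(sp$a, sp$c)
  # value at z = -beta is exactly one half, and curves rise in z
  at_half <- attraction_curves(dr, z_grid = -0.8)
  expect_equal(at_half$pi, rep(0.5, 3), tolerance = 1e-12)
  expect_true(all(tapply(cur$pi, cur$level, function(p) all(diff(p) > 0))))
})

test_that("window statistics average the curve over the stated window", {
  expect_equal(window_statistic(rep(0.5, 101), c(30, 50))$p_delta, 0.5)
  expect_equal(window_statistic(seq(0, 1, length.out = 101),
                                c(0, 100))$p_delta, 0.5)
  expect_equal(window_statistic(c(0.2, 0.4, 0.6), c(0, 2))$p_delta, 0.4)
  pi_c <- plogis(seq(-3, 3, length.out = 61))
  expect_equal(window_statistic(pi_c, c(0, 60))$p_delta, mean(pi_c))
  expect_error(window_statistic(pi_c, c(40, 30)), "empty")
  expect_error(window_statistic(pi_c, c(0, 80)), "support")
})

test_that("profile clustering separates and degenerates as designed", {
  base <- sin(seq(0, pi, length.out = 51))
  two <- rbind(matrix(rep(base, 3), 3, byrow = TRUE),
               matrix(rep(base + 4, 3), 3, byrow = TRUE))
  cl2 <- cluster_profiles(two, k = 2, smooth = FALSE)
  expect_equal(cl2$k, 2L)
  expect_equal(length(unique(cl2$assignments[1:3])), 1L)
  expect_equal(length(unique(cl2$assignments[4:6])), 1L)
  expect_gt(cl2$silhouette, 0.99)
  expect_warning(cl0 <- cluster_profiles(matrix(1, 5, 20)), "identical")
  expect_equal(cl0$k, 1L)
  # three well-separated bundles, automatic k
  set.seed(71)
  bundles <- do.call(rbind, lapply(c(-2, 0, 2), function(o)
    t(replicate(4, o + cumsum(rnorm(31, 0, 0.05))))))
  cla <- cluster_profiles(bundles, k = "auto")
  expect_equal(cla$k, 3L)
  expect_error(cluster_profiles(two, k = 10), "exceed")
  expect_error(cluster_profiles(two[1, , drop = FALSE]), "at least 2")
})
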