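test_that("uninformative measurements reduce the filter to the prior walk", {
  p <- suppressWarnings(model_params(gamma = rep(1, 3), delta = rep(0, 3),
                                     kappa1 = 5, kappa2 = 5,
                                     mu1 = pi / 4, mu2 = pi / 4,
                                     z0_var = 2, sigma = 0.7))
  set.seed(1)
  Y <- matrix(runif(4 * 51, 0, pi), 4, 51)
  fr <- ga_filter(Y, rep(1, 4), p)
  expect_lt(max(abs(fr$P_filt - (2 + (0:50) * 0.49))), 1e-10)
  expect_lt(max(abs(fr$m_filt)), 1e-10)
  expect_equal(fr$loglik, sum(vonmises_logdensity(Y, pi / 4, 5)),
               tolerance = 1e-10)
  # smoother: symmetric random walk keeps the prior mean everywhere
  sm <- ga_smoother(fr)
  expect_lt(max(abs(sm$m_smooth)), 1e-10)
  expect_equal(sm$m_smooth[51], sm$m_filt[51])
})

test_that("a subject without trials yields the pure prior recursion", {
  p <- model_params(gamma = 1, delta = 0)
  fr <- ga_filter(matrix(numeric(0), 0, 21), numeric(0), p)
  expect_equal(fr$loglik, 0)
  expect_equal(fr$P_filt, 1 + 0:20)
  expect_equal(fr$m_filt, rep(0, 21))
})

test_that("filter matches the particle-filter oracle on informative data", {
  sc <- small_scenario()
  sim <- simulate_dataset(sc)
  beta <- stimuli_equation(sc$design, sc$theta)
  Yu <- unclass(sim$Y)
  for (i in 1:2) {
    Yi <- matrix(Yu[i, , ], 4, 51)
    ga <- ga_filter(Yi, beta, sc$theta)
    pf <- particle_loglik(Yi, beta, sc$theta, n_particles = 2e4,
                          seed = 100 + i)
    expect_lt(abs(ga$loglik - pf$loglik),
              max(3 * pf$se, 0.005 * abs(pf$loglik)))
  }
})

test_that("particle filter is reproducible and obeys Monte Carlo scaling", {
  sc <- small_scenario(N = 20)
  sim <- simulate_dataset(sc)
  beta <- stimuli_equation(sc$design, sc$theta)
  Yi <- matrix(unclass(sim$Y)[1, , ], 4, 21)
  a <- particle_loglik(Yi, beta, sc$theta, n_particles = 5000, seed = 5)
  b <- particle_loglik(Yi, beta, sc$theta, n_particles = 5000, seed = 5)
  expect_identical(a, b)
  # uninformative limit: estimator matches the closed form within 3 SE
  pu <- suppressWarnings(model_params(gamma = rep(0.5, 2),
                                      delta = rep(0, 2),
                                      kappa1 = 4, kappa2 = 4,
                                      mu1 = 0.8, mu2 = 0.8))
  pfu <- particle_loglik(Yi, beta, pu, n_particles = 5000, seed = 2)
  expect_lt(abs(pfu$loglik - sum(vonmises_logdensity(Yi, 0.8, 4))),
            max(3 * pfu$se, 1e-8))
  # doubling particles shrinks the spread by about sqrt(2)
  est <- function(np) vapply(1:14, function(s)
    particle_loglik(Yi, beta, sc$theta, n_particles = np,
                    seed = 1000 + s)$loglik, numeric(1))
  r <- sd(est(2000)) / sd(est(8000))
  expect_gt(r, 1.2)  # expected 2 for a 4x particle increase
  expect_error(particle_loglik(Yi, beta, sc$theta, n_particles = 50),
               "100")
})

test_that("smoothing never inflates uncertainty and matches a dense oracle", {
  # informative case: smoothed variances cannot exceed filtered ones
  sc <- small_scenario()
  sim <- simulate_dataset(sc)
  beta <- stimuli_equation(sc$design, sc$theta)
  fr <- ga_smoother(ga_filter(matrix(unclass(sim$Y)[1, , ], 4, 51),
                              beta, sc$theta))
  expect_true(all(fr$P_smooth <= fr$P_filt + 1e-10))
  expect_true(all(fr$P_filt <= (1 + 0:50) + 1e-10)) # prior bounds filter
  # exact linear-Gaussian check on N = 5: Kalman moments fed through the
  # backward recursion must equal the joint-covariance solution
  n1 <- 6; R <- 0.8; yobs <- c(0.3, -0.2, 0.5, 1.1, 0.4, 0.9)
  m <- P <- mp <- Pp <- numeric(n1)
  for (n in 1:n1) {
    mp[n] <- if (n == 1) 0 else m[n - 1]
    Pp[n] <- if (n == 1) 1 else P[n - 1] + 1
    K <- Pp[n] / (Pp[n] + R)
    m[n] <- mp[n] + K * (yobs[n] - mp[n])
    P[n] <- (1 - K) * Pp[n]
  }
  fr2 <- structure(list(m_filt = m, P_filt = P, m_pred = mp, P_pred = Pp,
                        loglik = 0, m_smooth = NULL, P_smooth = NULL,
                        sigma = 1), class = "filter_result")
  sm <- ga_smoother(fr2)
  # dense joint precision of the random walk + observations
  Q <- diag(0, n1)
  Q[1, 1] <- 1
  for (n in 2:n1) {
    Q[n, n] <- Q[n, n] + 1; Q[n - 1, n - 1] <- Q[n - 1, n - 1] + 1
    Q[n, n - 1] <- Q[n, n - 1] - 1; Q[n - 1, n] <- Q[n - 1, n] - 1
  }
  Q <- Q + diag(1 / R, n1)
  V <- solve(Q)
  mu <- V %*% (yobs / R)
  expect_equal(sm$m_smooth, as.numeric(mu), tolerance = 1e-10)
  expect_equal(sm$P_smooth, diag(V), tolerance = 1e-10)
  expect_error(ga_smoother(list()), "ga_filter")
})

test_that("marginal log-likelihood responds continuously to kappa", {
  sc <- small_scenario(N = 30)
  sim <- simulate_dataset(sc)
  beta <- stimuli_equation(sc$design, sc$theta)
  Yi <- matrix(unclass(sim$Y)[1, , ], 4, 31)
  base <- ga_filter(Yi, beta, sc$theta)$loglik
  p2 <- sc$theta; p2$kappa1 <- p2$kappa1 + 1e-6
  expect_lt(abs(ga_filter(Yi, beta, p2)$loglik - base), 1e-3)
})
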