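test_that("transition density is the Gaussian random-walk kernel", {
  expect_equal(transition_logdensity(0, 0, 1), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(transition_logdensity(1, 0, 1),
               log(1 / sqrt(2 * pi)) - 0.5, tolerance = 1e-12)
  expect_equal(transition_logdensity(0.3, -1.1, 2),
               transition_logdensity(-1.1, 0.3, 2))
  expect_error(transition_logdensity(0, 0, 0), "positive")
})

test_that("von Mises log-density matches series and quadrature oracles", {
  expect_equal(vonmises_logdensity(1.3, 0.2, 0), log(1 / (2 * pi)),
               tolerance = 1e-12)
  # I0 by power series: I0(x) = sum (x^2/4)^m / (m!)^2
  i0_series <- function(x) sum((x^2 / 4)^(0:30) / factorial(0:30)^2)
  expect_equal(vonmises_logdensity(0.7, 0.7, 2),
               2 - log(2 * pi * i0_series(2)), tolerance = 1e-10)
  # normalization to 1 over a 2 pi interval
  for (k in c(0.1, 1, 10, 100)) {
    z <- integrate(function(y) exp(vonmises_logdensity(y, 0.5, k)),
                   0.5 - pi, 0.5 + pi, rel.tol = 1e-12)$value
    expect_equal(z, 1, tolerance = 1e-10)
  }
  expect_error(vonmises_logdensity(0, 0, -1), "non-negative")
})

test_that("mixture density interpolates its components on the log scale", {
  p <- model_params(kappa1 = 3, kappa2 = 8)
  y <- seq(0, pi, length.out = 9)
  expect_equal(mixture_logdensity(y, 1, p),
               vonmises_logdensity(y, p$mu1, p$kappa1))
  expect_equal(mixture_logdensity(y, 0, p),
               vonmises_logdensity(y, p$mu2, p$kappa2))
  peq <- suppressWarnings(model_params(kappa1 = 5, kappa2 = 5,
                                       mu1 = 1, mu2 = 1))
  expect_equal(mixture_logdensity(y, 0.5, peq),
               vonmises_logdensity(y, 1, 5))
  # bounded by the component log-densities
  l1 <- vonmises_logdensity(y, p$mu1, p$kappa1)
  l2 <- vonmises_logdensity(y, p$mu2, p$kappa2)
  lm <- mixture_logdensity(y, 0.3, p)
  expect_true(all(lm >= pmin(l1, l2) - 1e-12))
  expect_true(all(lm <= pmax(l1, l2) + 1e-12))
  expect_error(mixture_logdensity(y, 1.2, p), "\\[0, 1\\]")
})

test_that("attraction probability is a correctly oriented logistic", {
  expect_identical(attraction_prob(0, 0), 0.5)
  expect_equal(attraction_prob(1.32, 0), 1 / (1 + exp(-1.32)),
               tolerance = 1e-15)
  expect_equal(attraction_prob(1000, 0), 1)
  expect_equal(attraction_prob(-1000, 0), 0)
  z <- seq(-5, 5, 0.5)
  expect_true(all(diff(attraction_prob(0.3, z)) > 0))
  expect_true(all(diff(attraction_prob(0.3, z, "reversed")) < 0))
  expect_equal(attraction_prob(2, -2), 0.5)
  expect_equal(attraction_prob(1.32, 0, "reversed"),
               1 - attraction_prob(1.32, 0))
})

test_that("the stimuli equation reproduces hand-computed coefficients", {
  lev <- rep(c("HF", "LF", "NW"), times = c(2, 2, 2))
  # categorical only, posterior-mean magnitudes
  d1 <- design_spec(lev, active = "categorical")
  p1 <- model_params(gamma = c(1.323, 1.337, 1.310), delta = rep(0, 3))
  expect_equal(stimuli_equation(d1, p1),
               rep(c(1.323, 1.337, 1.310), each = 2))
  # covariate only: x = 0 gives 0
  d2 <- design_spec(lev, x = c(0, 1, 0, -1, 2, 0), active = "covariate")
  p2 <- model_params(eta = 0.078)
  expect_equal(stimuli_equation(d2, p2),
               0.078 * c(0, 1, 0, -1, 2, 0))
  # full interaction at x = 1, level 1: gamma1 + eta + delta1(=0)
  d3 <- design_spec(lev, x = rep(1, 6),
                    active = c("categorical", "covariate", "interaction"))
  p3 <- model_params(gamma = c(0.341, 1.300, 1.314),
                     delta = c(0, -0.385, -0.336), eta = 0.402)
  expect_equal(stimuli_equation(d3, p3)[1], 0.341 + 0.402)
  expect_equal(stimuli_equation(d3, p3)[3], 1.300 + 0.402 - 0.385)
  # identity partition: one free coefficient per trial
  did <- design_spec(paste0("t", 1:5), active = "categorical")
  expect_equal(dim(did$D), c(5, 5))
  g <- rnorm(5)
  expect_equal(stimuli_equation(did, model_params(gamma = g,
                                                  delta = rep(0, 5))), g)
  expect_error(design_spec(lev, active = c("covariate")), "absent")
  expect_error(design_spec(lev, x = 1:6, active = "interaction"),
               "requires")
})

test_that("complete-data log-likelihood follows the model factorization", {
  # one subject, one trial, two steps, uninformative measurement
  peq <- suppressWarnings(model_params(gamma = 0.4, delta = 0,
                                       kappa1 = 2, kappa2 = 2,
                                       mu1 = 0.9, mu2 = 0.9))
  des1 <- design_spec("a", active = "categorical")
  Z <- matrix(c(0.2, 0.7), 1, 2)
  Y <- angle_dataset(array(c(0.5, 1.1), dim = c(1, 1, 2)))
  by_hand <- dnorm(0.2, 0, 1, log = TRUE) +
    dnorm(0.7, 0.2, 1, log = TRUE) +
    vonmises_logdensity(0.5, 0.9, 2) + vonmises_logdensity(1.1, 0.9, 2)
  expect_equal(complete_data_loglik(Z, Y, des1, peq), by_hand,
               tolerance = 1e-12)
  # uniform measurement (kappa = 0): invariant to shifting all angles
  p0 <- suppressWarnings(model_params(gamma = 0.4, delta = 0,
                                      kappa1 = 1e-12, kappa2 = 1e-12))
  Y2 <- angle_dataset(array(runif(8, 0, 2), dim = c(2, 2, 2)))
  des2 <- design_spec(c("a", "b"), active = "categorical")
  p0$gamma <- c(0.4, -0.2)
  Z2 <- matrix(rnorm(4), 2, 2)
  Y2s <- angle_dataset(unclass(Y2) + 0.5)
  expect_equal(complete_data_loglik(Z2, Y2, des2, p0),
               complete_data_loglik(Z2, Y2s, des2, p0),
               tolerance = 1e-6)
  # duplicating a trial adds exactly its measurement contribution
  p <- model_params(gamma = c(0.5, 0.5), delta = c(0, 0))
  ll1 <- complete_data_loglik(Z2, Y2, des2, p)
  Y3 <- angle_dataset(unclass(Y2)[, c(1, 2, 2), , drop = FALSE])
  des3 <- design_spec(c("a", "b", "b"), active = "categorical")
  ll2 <- complete_data_loglik(Z2, Y3, des3, p)
  beta2 <- stimuli_equation(des2, p)
  contrib <- sum(mixture_logdensity(unclass(Y2)[, 2, ],
                                    plogis(beta2[2] + Z2), p))
  expect_equal(ll2 - ll1, contrib, tolerance = 1e-10)
  # literal per-trial counting multiplies the state terms by J
  state_part <- sum(dnorm(Z2[, 1], 0, 1, log = TRUE)) +
    sum(dnorm(Z2[, 2], Z2[, 1], 1, log = TRUE))
  expect_equal(complete_data_loglik(Z2, Y2, des2, p, "per_trial") -
                 complete_data_loglik(Z2, Y2, des2, p),
               state_part, tolerance = 1e-10)
  expect_error(complete_data_loglik(Z2[1, , drop = FALSE], Y2, des2, p),
               "I x")
})
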