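#' Sampler configuration
#'
#' Settings of the adaptive marginal Metropolis-Hastings sampler.
#' Defaults mirror a full-scale analysis (20 chains x 10,000 iterations,
#' burn-in 2,500, adaptation every 25 iterations, independent N(0, 25)
#' priors on every working-scale coordinate); scale them down for quick
#' runs.
#'
#' @param n_chains number of chains.
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations; proposal-covariance
#'   adaptation runs only during this phase.
#' @param adapt_interval re-estimate the proposal covariance from the
#'   chain history every this many iterations (the adaptation interval H).
#' @param prior_sd prior standard deviation on each working-scale
#'   coordinate (gamma, delta, eta, log kappa); default 5 (variance 25).
#' @param seed integer base seed; chain c uses `seed + c`.
#' @param n_quad base quadrature points per filter update (the filter's
#'   per-step resolution).
#' @param thin_latent thinning interval for the latent-path summaries.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(n_chains = 20, n_iter = 10000,
                             burn_in = 2500, adapt_interval = 25,
                             prior_sd = 5, seed = 1L, n_quad = 51,
                             thin_latent = 10) {
  stopifnot(burn_in < n_iter, adapt_interval >= 1, prior_sd > 0,
            n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 adapt_interval = as.integer(adapt_interval),
                 prior_sd = prior_sd, seed = as.integer(seed),
                 n_quad = as.integer(n_quad),
                 thin_latent = as.integer(thin_latent)),
            class = "inference_config")
}

# internal: layout of the sampled working-scale vector for a design.
# Order: gamma (K, categorical active), eta (covariate active),
# delta_2..K (interaction active), log kappa1, log kappa2 (unless fixed).
param_layout <- function(design, fix_kappa = NULL) {
  nm <- character(0)
  if ("categorical" %in% design$active)
    nm <- c(nm, paste0("gamma", seq_len(design$K)))
  if ("covariate" %in% design$active) nm <- c(nm, "eta")
  if ("interaction" %in% design$active && design$K > 1)
    nm <- c(nm, paste0("delta", 2:design$K))
  if (is.null(fix_kappa)) nm <- c(nm, "log_kappa1", "log_kappa2")
  nm
}

# internal: working-scale vector -> model_params
theta_to_params <- function(theta, design, base, fix_kappa = NULL) {
  nm <- param_layout(design, fix_kappa)
  stopifnot(length(theta) == length(nm))
  theta <- setNames(as.numeric(theta), nm)
  gamma <- rep(0, design$K)
  delta <- rep(0, design$K)
  eta <- 0
  if ("categorical" %in% design$active)
    gamma <- unname(theta[paste0("gamma", seq_len(design$K))])
  if ("covariate" %in% design$active) eta <- unname(theta["eta"])
  if ("interaction" %in% design$active && design$K > 1)
    delta[2:design$K] <- unname(theta[paste0("delta", 2:design$K)])
  if (is.null(fix_kappa)) {
    k1 <- exp(unname(theta["log_kappa1"]))
    k2 <- exp(unname(theta["log_kappa2"]))
  } else {
    k1 <- fix_kappa[1]; k2 <- fix_kappa[2]
  }
  model_params(gamma = gamma, delta = delta, eta = eta,
               kappa1 = k1, kappa2 = k2,
               mu1 = base$mu1, mu2 = base$mu2, sigma = base$sigma,
               z0_mean = base$z0_mean, z0_var = base$z0_var,
               sign_convention = base$sign_convention)
}

#' Observed (static) mixture log-likelihood
#'
#' The likelihood of the measurement mixture with the latent state fixed
#' at 0, so the mixing probability depends on the stimuli equation only.
#' Used to initialize the sampler and to build its starting proposal
#' covariance.
#'
#' @param theta working-scale parameter vector (see details in
#'   [run_mh()]).
#' @param Y an [angle_dataset()].
#' @param design a [design_spec()].
#' @param base a [model_params()] supplying the fixed quantities.
#' @param fix_kappa optional length-2 numeric fixing the concentrations.
#' @return Scalar log-likelihood.
#' @export
static_loglik <- function(theta, Y, design, base, fix_kappa = NULL) {
  p <- tryCatch(theta_to_params(theta, design, base, fix_kappa),
                error = function(e) NULL)
  if (is.null(p)) return(-Inf)
  beta <- stimuli_equation(design, p)
  pi_j <- attraction_prob(beta, 0, p$sign_convention)
  Yu <- unclass(Y)
  total <- 0
  for (j in seq_len(dim(Yu)[2]))
    total <- total + sum(mixture_logdensity(Yu[, j, ], pi_j[j], p))
  if (!is.finite(total)) -Inf else total
}

#' Starting values for the sampler
#'
#' Numerically maximizes the static mixture posterior — the mixture
#' likelihood with the latent state fixed at 0, plus the sampler's
#' N(0, prior_sd^2) working-scale prior — with multiple jittered starts
#' to avoid local optima. The prior term is negligible wherever the data
#' are informative and keeps the starting point finite when they are
#' not (e.g. near-zero concentrations).
#'
#' @inheritParams static_loglik
#' @param n_starts number of optimization starts.
#' @param seed RNG seed for the start jitter.
#' @param prior_sd prior standard deviation on each working-scale
#'   coordinate; default 5.
#' @return A list with `theta` (working scale), `params` (a
#'   [model_params()]), and `value` (maximized penalized
#'   log-likelihood).
#' @export
initialize_params <- function(Y, design, base = NULL, fix_kappa = NULL,
                              n_starts = 5, seed = 1L, prior_sd = 5) {
  if (is.null(base))
    base <- model_params(gamma = rep(0, design$K),
                         delta = rep(0, design$K))
  nm <- param_layout(design, fix_kappa)
  d <- length(nm)
  set.seed(seed)
  center <- setNames(rep(0, d), nm)
  if (is.null(fix_kappa))
    center[c("log_kappa1", "log_kappa2")] <- log(10)
  fn <- function(th) -static_loglik(th, Y, design, base, fix_kappa) -
    sum(dnorm(th, 0, prior_sd, log = TRUE))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- center + if (s == 1) 0 else rnorm(d, 0, 0.75)
    fit <- tryCatch(
      optim(start, fn, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fit <- tryCatch(
        optim(fit$par, fn, method = "BFGS",
              control = list(maxit = 200)),
        error = function(e) fit)
    }
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("initialization failed on all starts")
  theta <- setNames(best$par, nm)
  list(theta = theta,
       params = theta_to_params(theta, design, base, fix_kappa),
       value = -best$value)
}

#' Starting proposal covariance
#'
#' Inverse of the negative finite-difference Hessian of the static
#' observed likelihood at the starting values, regularized to be positive
#' definite by flooring the eigenvalues of the negative Hessian at 1e-8.
#'
#' The static likelihood conditions on z = 0 and therefore carries no
#' variance along the weakly identified direction in which a constant
#' shift of all gamma coefficients trades against a shift of every
#' latent path (a trade whose only cost is the initial-state prior, with
#' marginal variance about `z0_var / I`). That variance is added to the
#' gamma block so the sampler can explore the direction from the start.
#'
#' @param theta0 working-scale starting values from
#'   [initialize_params()].
#' @inheritParams static_loglik
#' @param prior_sd prior standard deviation; its curvature
#'   `1/prior_sd^2` is added to the negative Hessian (a Laplace
#'   approximation of the static posterior), which keeps the proposal
#'   on the prior scale when the data leave directions flat.
#' @return A symmetric positive-definite matrix.
#' @export
initial_proposal_cov <- function(theta0, Y, design, base = NULL,
                                 fix_kappa = NULL, prior_sd = 5) {
  if (is.null(base))
    base <- model_params(gamma = rep(0, design$K),
                         delta = rep(0, design$K))
  f <- function(th) static_loglik(th, Y, design, base, fix_kappa) +
    sum(dnorm(th, 0, prior_sd, log = TRUE))
  S <- neg_hessian_inverse(f, as.numeric(theta0))
  nm <- param_layout(design, fix_kappa)
  if ("categorical" %in% design$active) {
    u <- as.numeric(grepl("^gamma", nm))
    S <- S + (base$z0_var / dim(Y)[1]) * tcrossprod(u)
  }
  S
}

# internal: regularized inverse negative Hessian of a log-density
# (finite differences; eigenvalue floor 1e-8 keeps the result positive
# definite even for singular curvature)
neg_hessian_inverse <- function(f, x0) {
  H <- pracma::hessian(f, x0)
  if (!all(is.finite(H))) stop("non-finite Hessian entries at theta0")
  A <- -(H + t(H)) / 2
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  S <- eg$vectors %*% diag(1 / lam, length(lam)) %*% t(eg$vectors)
  (S + t(S)) / 2
}

#' Adaptive marginal Metropolis-Hastings sampler
#'
#' Samples the posterior of the working-scale parameter vector (gamma per
#' active factor level, covariate slope eta, interaction contrasts
#' delta_2..K — delta_1 is fixed at 0 and excluded — and log kappa1, log
#' kappa2) under independent N(0, prior_sd^2) priors. The target density
#' marginalizes the latent paths through the Gaussian-approximation
#' filter: log target = sum over subjects of the filter log-likelihood
#' plus the log prior. Proposals are Gaussian random walks with
#' covariance (2.38^2 / d) * Sigma_t, where Sigma_t starts at the
#' Hessian-based covariance of [initial_proposal_cov()] and is
#' re-estimated from the chain history every `adapt_interval` iterations
#' during burn-in only (adaptation is frozen afterwards so kept draws
#' target a fixed kernel). A filter failure at a proposal rejects the
#' proposal with a warning rather than aborting the chain.
#'
#' @param Y an [angle_dataset()], or a plain I x J x (N + 1) array of
#'   radians (e.g. unfolded draws from [simulate_angles()]).
#' @param design a [design_spec()].
#' @param config an [inference_config()].
#' @param base a [model_params()] supplying fixed quantities (mu1, mu2,
#'   sigma, initial-state prior, sign convention); estimated entries are
#'   ignored.
#' @param fix_kappa optional length-2 numeric: fix the concentrations at
#'   these values and exclude them from sampling.
#' @param init optional list with `theta` and `Sigma0` to skip the
#'   initialization stage.
#' @param latent logical: compute posterior-mean smoothed latent paths
#'   from kept draws (thinned by `config$thin_latent`)? Default TRUE.
#' @return An object of class `mh_draws`: `draws` (chains x kept x d
#'   array, working scale), `param_names`, `acceptance_rate` per chain,
#'   `latent_summaries` (I x (N+1) matrix of posterior-mean smoothed
#'   paths, or NULL), plus the configuration and design.
#' @export
run_mh <- function(Y, design, config = inference_config(), base = NULL,
                   fix_kappa = NULL, init = NULL, latent = TRUE) {
  if (is.null(base))
    base <- model_params(gamma = rep(0, design$K),
                         delta = rep(0, design$K))
  nm <- param_layout(design, fix_kappa)
  d <- length(nm)
  if (is.null(init)) {
    ip <- initialize_params(Y, design, base, fix_kappa,
                            seed = config$seed,
                            prior_sd = config$prior_sd)
    theta0 <- ip$theta
    Sigma0 <- tryCatch(
      initial_proposal_cov(theta0, Y, design, base, fix_kappa,
                           prior_sd = config$prior_sd),
      error = function(e) {
        warning("falling back to a prior-scale starting proposal: ",
                conditionMessage(e), call. = FALSE)
        diag(config$prior_sd^2, d)
      })
  } else {
    theta0 <- setNames(as.numeric(init$theta), nm)
    Sigma0 <- init$Sigma0
  }

  log_target <- function(th) {
    lp <- sum(dnorm(th, 0, config$prior_sd, log = TRUE))
    p <- tryCatch(theta_to_params(th, design, base, fix_kappa),
                  error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    ll <- tryCatch(model_loglik(Y, design, p, config$n_quad),
                   error = function(e) {
                     warning("filter failure at a proposal: ",
                             conditionMessage(e), call. = FALSE)
                     -Inf
                   })
    ll + lp
  }

  scale <- 2.38^2 / d
  n_kept <- config$n_iter - config$burn_in
  draws <- array(NA_real_, dim = c(config$n_chains, n_kept, d),
                 dimnames = list(NULL, NULL, nm))
  acc_rate <- numeric(config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    L <- chol(scale * Sigma0 + diag(1e-12, d))
    # jittered start with a finite target
    theta <- as.numeric(theta0)
    lt <- log_target(theta)
    for (try in 1:20) {
      cand <- as.numeric(theta0) + 0.1 * drop(rnorm(d) %*% L)
      ltc <- log_target(cand)
      if (is.finite(ltc)) { theta <- cand; lt <- ltc; break }
    }
    if (!is.finite(lt)) stop("could not find a finite starting point")

    history <- matrix(NA_real_, config$n_iter, d)
    n_acc <- 0L
    n_acc_win <- 0L
    lsf <- 0   # log scale factor, tuned toward 25% acceptance
    kept_i <- 0L
    for (t in seq_len(config$n_iter)) {
      prop <- theta + drop(rnorm(d) %*% L)
      ltp <- log_target(prop)
      if (is.finite(ltp) && log(runif(1)) < ltp - lt) {
        theta <- prop; lt <- ltp
        n_acc <- n_acc + 1L
        n_acc_win <- n_acc_win + 1L
      }
      history[t, ] <- theta
      if (t <= config$burn_in && t %% config$adapt_interval == 0) {
        # covariance from the chain history plus a global scale factor
        # nudged toward the 25% random-walk acceptance target; both are
        # frozen once burn-in ends
        lsf <- max(-4, min(4, lsf +
                             (n_acc_win / config$adapt_interval - 0.25)))
        n_acc_win <- 0L
        if (t >= max(2 * d, 10)) {
          S <- cov(history[seq_len(t), , drop = FALSE]) + diag(1e-8, d)
          L <- tryCatch(chol(scale * exp(lsf) * S),
                        error = function(e) L)
        }
      }
      if (t > config$burn_in) {
        kept_i <- kept_i + 1L
        draws[ch, kept_i, ] <- theta
      }
    }
    acc_rate[ch] <- n_acc / config$n_iter
  }
  if (any(acc_rate < 0.1 | acc_rate > 0.5))
    warning("post-adaptation acceptance rate outside [0.1, 0.5] for ",
            sum(acc_rate < 0.1 | acc_rate > 0.5), " chain(s)",
            call. = FALSE)

  out <- structure(list(draws = draws, param_names = nm,
                        acceptance_rate = acc_rate, config = config,
                        design = design, base = base,
                        fix_kappa = fix_kappa, theta0 = theta0,
                        Sigma0 = Sigma0, latent_summaries = NULL),
                   class = "mh_draws")
  if (latent) out$latent_summaries <- latent_summaries(out, Y)
  out
}

# internal: pooled kept draws as (chains * kept) x d matrix
pooled_draws <- function(fit) {
  d <- dim(fit$draws)
  out <- matrix(aperm(fit$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(out) <- fit$param_names
  out
}

#' Posterior-mean smoothed latent paths
#'
#' Point estimates of each subject's latent movement path: for a thinned
#' subset of kept draws, run the Gaussian-approximation filter and
#' backward smoother and average the smoothed means.
#'
#' @param fit an `mh_draws` object.
#' @param Y the [angle_dataset()] the model was fitted to.
#' @param thin thinning interval; defaults to the configuration's
#'   `thin_latent`.
#' @return Numeric I x (N + 1) matrix of posterior-mean smoothed paths.
#' @export
latent_summaries <- function(fit, Y, thin = fit$config$thin_latent) {
  pool <- pooled_draws(fit)
  idx <- seq(1, nrow(pool), by = thin)
  d <- dim(Y)
  Yu <- unclass(Y)
  acc <- matrix(0, d[1], d[3])
  for (r in idx) {
    p <- theta_to_params(pool[r, ], fit$design, fit$base, fit$fix_kappa)
    beta <- stimuli_equation(fit$design, p)
    for (i in seq_len(d[1])) {
      fr <- ga_smoother(ga_filter(matrix(Yu[i, , ], d[2], d[3]), beta, p,
                                  n_quad = fit$config$n_quad))
      acc[i, ] <- acc[i, ] + fr$m_smooth
    }
  }
  acc / length(idx)
}

#' Gelman-Rubin convergence diagnostics
#'
#' Classic between/within-chain potential scale reduction factor per
#' parameter, plus an autocorrelation-based effective sample size.
#' Chains that are all identical constants report R-hat = 1 by
#' convention.
#'
#' @param fit an `mh_draws` object with at least 2 chains and 10 kept
#'   draws per chain.
#' @return A data frame (class `mh_diagnostics`) with columns
#'   `parameter`, `rhat`, `ess`.
#' @export
gelman_rubin <- function(fit) {
  dms <- dim(fit$draws)
  if (dms[1] < 2)
    stop("at least 2 chains are required; for a single chain, split it ",
         "into halves and diagnose those")
  if (dms[2] < 10) stop("need at least 10 kept draws per chain")
  m <- dms[1]; n <- dms[2]
  out <- data.frame(parameter = fit$param_names,
                    rhat = NA_real_, ess = NA_real_)
  for (k in seq_len(dms[3])) {
    ch <- fit$draws[, , k, drop = FALSE][, , 1]      # m x n
    means <- rowMeans(ch)
    vars <- apply(ch, 1, var)
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) {
      out$rhat[k] <- 1
      out$ess[k] <- if (B <= 0) m * n else m
      next
    }
    var_plus <- (n - 1) / n * W + B / n
    out$rhat[k] <- sqrt(var_plus / W)
    # ESS: mean per-chain autocorrelation, truncated at first negative lag
    max_lag <- min(n - 1, 200)
    rho <- rowMeans(vapply(seq_len(m), function(c_) {
      a <- acf(ch[c_, ], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1]
      a[!is.finite(a)] <- 0
      a
    }, numeric(max_lag)))
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    out$ess[k] <- m * n / (1 + 2 * sum(rho))
  }
  class(out) <- c("mh_diagnostics", "data.frame")
  out
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, the asymmetric interval (q0.05, q0.975)
#' used in reporting (note it spans 92.5% probability), and the
#' Gelman-Rubin statistic. Concentrations are back-transformed to the
#' natural kappa scale before summarizing.
#'
#' @param fit an `mh_draws` object.
#' @return A data frame with columns `parameter`, `q0.05`, `mean`,
#'   `q0.975`, `rhat`.
#' @export
posterior_summary <- function(fit) {
  pool <- pooled_draws(fit)
  rhat <- tryCatch(gelman_rubin(fit)$rhat,
                   error = function(e) rep(NA_real_, ncol(pool)))
  nat <- pool
  nm <- fit$param_names
  for (k in c("log_kappa1", "log_kappa2")) {
    i <- match(k, nm)
    if (!is.na(i)) {
      nat[, i] <- exp(nat[, i])
      nm[i] <- sub("log_", "", k)
    }
  }
  data.frame(parameter = nm,
             q0.05 = apply(nat, 2, quantile, 0.05),
             mean = colMeans(nat),
             q0.975 = apply(nat, 2, quantile, 0.975),
             rhat = rhat, row.names = NULL)
}

#' @export
print.mh_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Marginal Metropolis-Hastings draws:", d[1], "chains x", d[2],
      "kept iterations x", d[3], "parameters\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat("  acceptance rates:",
      paste(sprintf("%.2f", x$acceptance_rate), collapse = " "), "\n")
  invisible(x)
}
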