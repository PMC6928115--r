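#' Experimental design specification
#'
#' Encodes the trial-level experimental design entering the stimuli
#' equation: a J x K Boolean partition matrix `D` assigning each trial to
#' one level of a categorical factor, an optional length-J continuous
#' covariate `x`, and flags saying which terms of the linear predictor are
#' active (categorical, covariate, interaction).
#'
#' @param level length-J vector (factor, character or integer) giving each
#'   trial's level of the categorical factor; levels are mapped to columns
#'   of `D` in first-appearance order.
#' @param x optional length-J numeric covariate.
#' @param active character vector naming the active terms, a subset of
#'   `c("categorical", "covariate", "interaction")`. `"interaction"`
#'   requires both other terms.
#' @return An object of class `design_spec` with fields `D`, `x`,
#'   `active`, `level_labels`, `J`, `K`.
#' @examples
#' design_spec(rep(c("HF", "LF", "NW"), each = 4), x = rnorm(12),
#'             active = c("categorical", "covariate", "interaction"))
#' @export
design_spec <- function(level, x = NULL,
                        active = "categorical") {
  active <- match.arg(active,
                      c("categorical", "covariate", "interaction"),
                      several.ok = TRUE)
  if ("interaction" %in% active &&
      !all(c("categorical", "covariate") %in% active))
    stop("an active interaction requires both categorical and covariate terms")
  labels <- unique(as.character(level))
  J <- length(level)
  K <- length(labels)
  if (K > J) stop("more levels than trials")
  D <- matrix(0L, J, K, dimnames = list(NULL, labels))
  D[cbind(seq_len(J), match(as.character(level), labels))] <- 1L
  if (any(c("covariate", "interaction") %in% active)) {
    if (is.null(x)) stop("covariate term active but `x` is absent")
    if (length(x) != J) stop("`x` must have one value per trial")
    if (!all(is.finite(x))) stop("covariate must be finite")
  }
  structure(list(D = D, x = if (is.null(x)) NULL else as.numeric(x),
                 active = active, level_labels = labels, J = J, K = K),
            class = "design_spec")
}

#' Read a trial design file
#'
#' Delimited text with header `trial,level` and optionally `x`; level
#' strings are mapped to partition-matrix columns in first-appearance
#' order.
#'
#' @param path file path.
#' @param active active terms, as in [design_spec()].
#' @return A `design_spec`.
#' @export
read_design <- function(path, active = "categorical") {
  df <- read.csv(path)
  if (!all(c("trial", "level") %in% names(df)))
    stop("design file must have columns trial, level")
  df <- df[order(df$trial), ]
  design_spec(df$level, x = if ("x" %in% names(df)) df$x else NULL,
              active = active)
}

#' Model parameters
#'
#' The full parameter set of the state-space model: the estimated stimuli
#' coefficients (`gamma` per factor level, covariate slope `eta`,
#' interaction contrasts `delta` with `delta[1]` fixed at 0) and von Mises
#' concentrations (`kappa1`, `kappa2`), plus fixed quantities: the
#' component mean directions `mu1`, `mu2` (the known screen positions of
#' the distractor and target labels), the transition standard deviation
#' `sigma`, the initial-state prior, and the orientation of the logistic
#' link.
#'
#' @param gamma numeric length-K, categorical coefficients (0 if the term
#'   is inactive).
#' @param delta numeric length-K interaction contrasts; `delta[1]` must
#'   be 0.
#' @param eta numeric scalar covariate slope.
#' @param kappa1,kappa2 positive von Mises concentrations of the
#'   distractor-side and target-side components.
#' @param mu1,mu2 fixed component mean directions in radians; defaults are
#'   the screen-corner directions 3*pi/4 (distractor, top-left) and pi/4
#'   (target, top-right).
#' @param sigma non-negative transition standard deviation of the latent
#'   AR(1) random walk; default 1 (0 is allowed for degenerate
#'   simulation only — the filter requires sigma > 0).
#' @param z0_mean,z0_var initial-state prior N(z0_mean, z0_var); defaults
#'   0 and 1.
#' @param sign_convention `"literal"` (attraction probability increases
#'   with beta + z) or `"reversed"` (decreases); see
#'   [attraction_prob()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(gamma = 0, delta = 0, eta = 0,
                         kappa1 = 20, kappa2 = 45,
                         mu1 = 3 * pi / 4, mu2 = pi / 4,
                         sigma = 1, z0_mean = 0, z0_var = 1,
                         sign_convention = "literal") {
  sign_convention <- match.arg(sign_convention, c("literal", "reversed"))
  if (!is.finite(kappa1) || !is.finite(kappa2) ||
      kappa1 <= 0 || kappa2 <= 0)
    stop("kappa1 and kappa2 must be positive and finite")
  if (sigma < 0) stop("sigma must be non-negative")
  if (z0_var <= 0) stop("z0_var must be positive")
  if (delta[1] != 0) stop("delta[1] is fixed at 0 for identifiability")
  if (mu1 == mu2)
    warning("mu1 == mu2: the two mixture components are indistinguishable")
  structure(list(gamma = as.numeric(gamma), delta = as.numeric(delta),
                 eta = as.numeric(eta)[1],
                 kappa1 = kappa1, kappa2 = kappa2, mu1 = mu1, mu2 = mu2,
                 sigma = sigma, z0_mean = z0_mean, z0_var = z0_var,
                 sign_convention = sign_convention),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("State-space model parameters\n")
  cat("  gamma :", paste(round(x$gamma, 3), collapse = " "), "\n")
  cat("  delta :", paste(round(x$delta, 3), collapse = " "), "\n")
  cat("  eta   :", round(x$eta, 3), "\n")
  cat("  kappa :", round(x$kappa1, 3), round(x$kappa2, 3), "\n")
  cat("  mu    :", round(x$mu1, 4), round(x$mu2, 4), " sigma:", x$sigma, "\n")
  invisible(x)
}

#' Log transition density of the latent AR(1) process
#'
#' The latent movement process is a Gaussian random walk:
#' z_n | z_(n-1) ~ N(z_(n-1), sigma^2).
#'
#' @param z_curr,z_prev current and previous latent states.
#' @param sigma positive transition standard deviation.
#' @return Log-density (vectorized).
#' @export
transition_logdensity <- function(z_curr, z_prev, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  dnorm(z_curr, mean = z_prev, sd = sigma, log = TRUE)
}

#' Log-density of the von Mises distribution
#'
#' log f(y; mu, kappa) = kappa*cos(y - mu) - log(2*pi*I0(kappa)), with I0
#' the modified Bessel function of order zero, evaluated stably for large
#' kappa via exponential scaling. kappa = 0 gives the uniform circle.
#'
#' @param y angle(s) in radians.
#' @param mu mean direction in radians.
#' @param kappa non-negative concentration.
#' @return Log-density (vectorized over `y`).
#' @export
vonmises_logdensity <- function(y, mu, kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  kappa * cos(y - mu) - log(2 * pi) - log_bessel_i0(kappa)
}

#' Log-density of the two-component von Mises mixture
#'
#' The measurement density: component 1 (mean `mu1`, concentration
#' `kappa1`) with mixing probability `pi_mix`, component 2 with
#' `1 - pi_mix`, combined on the log scale with a stable log-sum.
#'
#' @param y angle(s) in radians.
#' @param pi_mix mixing probability in \[0, 1\].
#' @param params a [model_params()] object.
#' @return Log-density (vectorized over `y` and `pi_mix`).
#' @export
mixture_logdensity <- function(y, pi_mix, params) {
  if (any(pi_mix < 0 | pi_mix > 1)) stop("pi_mix must lie in [0, 1]")
  la <- vonmises_logdensity(y, params$mu1, params$kappa1) + log(pi_mix)
  lb <- vonmises_logdensity(y, params$mu2, params$kappa2) + log1p(-pi_mix)
  m <- pmax(la, lb)
  # exact endpoints: log(0) terms drop out
  m[is.infinite(m)] <- 0
  m + log(exp(la - m) + exp(lb - m))
}

#' Attraction probability (logistic link)
#'
#' The step-wise probability that an observed angle is generated from the
#' distractor-side mixture component: `plogis(beta + z)` under the
#' `"literal"` convention, `plogis(-(beta + z))` under `"reversed"`. The
#' reversed convention matches reported probability graphs in which a
#' latent state shifted toward positive values corresponds to low
#' distractor activation.
#'
#' @param beta trial-level linear predictor.
#' @param z latent state.
#' @param sign_convention `"literal"` or `"reversed"`.
#' @return Probability in (0, 1), vectorized.
#' @export
attraction_prob <- function(beta, z, sign_convention = "literal") {
  plogis(sign_mult(sign_convention) * (beta + z))
}

#' Stimuli equation: trial-level linear predictor
#'
#' beta_j = sum_k d_jk gamma_k + x_j (eta + sum_k d_jk delta_k), with
#' inactive terms contributing zero. This linear predictor conveys the
#' experimental design (factor levels, covariate, interaction) into the
#' attraction probability.
#'
#' @param design a [design_spec()].
#' @param params a [model_params()]; `gamma` must have length K when the
#'   categorical term is active, `delta` length K when the interaction is
#'   active.
#' @return Numeric length-J vector of coefficients beta.
#' @export
stimuli_equation <- function(design, params) {
  stopifnot(inherits(design, "design_spec"))
  beta <- numeric(design$J)
  if ("categorical" %in% design$active) {
    if (length(params$gamma) != design$K)
      stop("gamma must have one coefficient per factor level")
    beta <- beta + as.vector(design$D %*% params$gamma)
  }
  if (any(c("covariate", "interaction") %in% design$active)) {
    if (is.null(design$x)) stop("covariate term active but x is absent")
    slope <- rep(0, design$J)
    if ("covariate" %in% design$active) slope <- slope + params$eta
    if ("interaction" %in% design$active) {
      if (length(params$delta) != design$K)
        stop("delta must have one contrast per factor level")
      slope <- slope + as.vector(design$D %*% params$delta)
    }
    beta <- beta + design$x * slope
  }
  beta
}

#' Complete-data log-likelihood
#'
#' Joint log-density of latent paths and observed angles: the
#' initial-state log-prior and AR(1) transition terms for each subject's
#' latent path, plus the mixture measurement terms over subjects, trials
#' and steps. By default the latent-path prior is counted once per subject
#' (the path is shared across that subject's trials);
#' `state_prior = "per_trial"` restores a J-fold counting of the state
#' terms.
#'
#' @param Z numeric I x (N + 1) matrix of latent paths.
#' @param Y an [angle_dataset()], I x J x (N + 1).
#' @param design a [design_spec()].
#' @param params a [model_params()].
#' @param state_prior `"once"` (default) or `"per_trial"`.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(Z, Y, design, params,
                                 state_prior = "once") {
  state_prior <- match.arg(state_prior, c("once", "per_trial"))
  Z <- as.matrix(Z)
  d <- dim(Y)
  if (nrow(Z) != d[1] || ncol(Z) != d[3])
    stop("Z must be I x (N+1), matching the angle dataset")
  if (design$J != d[2])
    stop("design has ", design$J, " trials but the dataset has ", d[2])
  beta <- stimuli_equation(design, params)
  n1 <- d[3]
  state_ll <- sum(dnorm(Z[, 1], params$z0_mean, sqrt(params$z0_var),
                        log = TRUE))
  if (n1 > 1)
    state_ll <- state_ll +
      sum(transition_logdensity(Z[, -1, drop = FALSE],
                                Z[, -n1, drop = FALSE], params$sigma))
  if (state_prior == "per_trial") state_ll <- state_ll * design$J
  meas_ll <- 0
  s <- sign_mult(params$sign_convention)
  for (j in seq_len(d[2])) {
    pij <- plogis(s * (beta[j] + Z))          # I x (N+1)
    meas_ll <- meas_ll +
      sum(mixture_logdensity(unclass(Y)[, j, ], pij, params))
  }
  state_ll + meas_ll
}
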