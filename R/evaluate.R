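#' Histogram-overlap fit index
#'
#' The bounded agreement index used by the posterior predictive check:
#' `100 * (1 - 0.5 * sum_b |h_obs(b) - h_rep(b)|)` between normalized
#' `n_bins`-bin histograms of two angle samples on \[0, pi\]. 100 means
#' identical binned distributions, 0 disjoint ones.
#'
#' @param obs,rep numeric vectors (or arrays) of angles in \[0, pi\].
#' @param n_bins number of bins; default 36.
#' @return Percentage in \[0, 100\].
#' @export
histogram_overlap <- function(obs, rep, n_bins = 36) {
  breaks <- seq(0, pi, length.out = n_bins + 1)
  bin <- function(a) pmin(pmax(findInterval(a, breaks,
                                            rightmost.closed = TRUE),
                               1L), n_bins)
  h1 <- tabulate(bin(as.numeric(obs)), n_bins)
  h2 <- tabulate(bin(as.numeric(rep)), n_bins)
  100 * (1 - 0.5 * sum(abs(h1 / sum(h1) - h2 / sum(h2))))
}

#' Posterior predictive goodness of fit
#'
#' Simulation-based model evaluation: draws `M` parameter vectors (with
#' replacement) from the kept posterior draws, simulates a full replicate
#' dataset for each (latent paths from each subject's smoothed posterior
#' by default, or fresh prior paths — see `latent`; angles from the
#' measurement mixture; same design and dimensions as the observed
#' data), and scores agreement between observed and replicate angle
#' distributions with a bounded histogram-overlap index,
#' `fit = 100 * (1 - 0.5 * sum_b |h_obs(b) - h_rep_bar(b)|)`,
#' where `h` are normalized 36-bin angle histograms on \[0, pi\] and
#' `h_rep_bar` averages the replicate histograms. 0 means disjoint
#' distributions, 100 a perfect match. The overall index pools all cells;
#' the by-subject index applies the same formula per subject and reports
#' each subject's value and their mean.
#'
#' @param fit an `mh_draws` object.
#' @param Y the observed [angle_dataset()].
#' @param design a [design_spec()] (defaults to the one stored in `fit`).
#' @param M number of replicate datasets; default 5000.
#' @param n_bins histogram bins on \[0, pi\]; default 36.
#' @param seed RNG seed for the replicate simulation.
#' @param latent `"posterior"` (default) draws each subject's replicate
#'   path from that subject's smoothed latent posterior (the joint
#'   posterior predictive, appropriate for subject-level checks);
#'   `"prior"` draws fresh paths from the AR(1) prior (the mixed
#'   predictive, which scores how well the marginal model reproduces a
#'   new subject rather than the observed ones).
#' @param n_latent_draws number of thinned parameter draws at which
#'   smoothed latent posteriors are computed for `latent = "posterior"`;
#'   default 50.
#' @return An object of class `fit_report`: `overall_fit`,
#'   `by_subject_fit` (vector), `by_subject_mean`, `M`.
#' @export
posterior_predictive_fit <- function(fit, Y, design = fit$design,
                                     M = 5000, n_bins = 36, seed = 1L,
                                     latent = c("posterior", "prior"),
                                     n_latent_draws = 50) {
  latent <- match.arg(latent)
  if (M < 100) stop("use at least 100 replicates")
  pool <- pooled_draws(fit)
  d <- dim(Y)
  I <- d[1]
  breaks <- seq(0, pi, length.out = n_bins + 1)
  bin_of <- function(a) pmin(pmax(findInterval(a, breaks,
                                               rightmost.closed = TRUE),
                                  1L), n_bins)
  Yu <- unclass(Y)
  h_obs_subj <- t(vapply(seq_len(I), function(i)
    tabulate(bin_of(Yu[i, , ]), n_bins), numeric(n_bins)))
  h_obs_subj <- h_obs_subj / rowSums(h_obs_subj)
  h_obs <- tabulate(bin_of(Yu), n_bins)
  h_obs <- h_obs / sum(h_obs)

  set.seed(seed)
  if (latent == "posterior") {
    # smoothed latent posteriors at a thinned subset of draws
    sub <- unique(round(seq(1, nrow(pool),
                            length.out = min(n_latent_draws,
                                             nrow(pool)))))
    smooth <- lapply(sub, function(r) {
      p <- theta_to_params(pool[r, ], design, fit$base, fit$fix_kappa)
      beta <- stimuli_equation(design, p)
      ms <- Ps <- matrix(0, I, d[3])
      for (i in seq_len(I)) {
        fr <- ga_smoother(ga_filter(matrix(Yu[i, , ], d[2], d[3]),
                                    beta, p))
        ms[i, ] <- fr$m_smooth
        Ps[i, ] <- fr$P_smooth
      }
      list(params = p, m = ms, P = Ps)
    })
    idx <- sample.int(length(sub), M, replace = TRUE)
  } else {
    idx <- sample.int(nrow(pool), M, replace = TRUE)
  }

  acc_subj <- matrix(0, I, n_bins)
  acc_all <- numeric(n_bins)
  sc <- structure(list(I = I, J = d[2], N = d[3] - 1,
                       design = design, seed = NULL),
                  class = "sim_scenario")
  for (r in idx) {
    if (latent == "posterior") {
      s <- smooth[[r]]
      sc$theta <- s$params
      Z <- s$m + sqrt(s$P) * matrix(rnorm(I * d[3]), I, d[3])
    } else {
      sc$theta <- theta_to_params(pool[r, ], design, fit$base,
                                  fit$fix_kappa)
      Z <- simulate_latent(sc, seed = NULL)
    }
    Yr <- unclass(simulate_angles(Z, sc))
    hr <- t(vapply(seq_len(I), function(i)
      tabulate(bin_of(Yr[i, , ]), n_bins), numeric(n_bins)))
    acc_subj <- acc_subj + hr / rowSums(hr)
    acc_all <- acc_all + colSums(hr) / sum(hr)
  }
  h_rep <- acc_all / M
  h_rep_subj <- acc_subj / M
  overall <- 100 * (1 - 0.5 * sum(abs(h_obs - h_rep)))
  by_subj <- 100 * (1 - 0.5 * rowSums(abs(h_obs_subj - h_rep_subj)))
  structure(list(overall_fit = overall, by_subject_fit = by_subj,
                 by_subject_mean = mean(by_subj), M = M,
                 n_bins = n_bins, latent = latent),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Posterior predictive fit (histogram-overlap index, M =", x$M,
      "replicates)\n")
  cat(sprintf("  overall fit    : %.1f%%\n", x$overall_fit))
  cat(sprintf("  by-subject fit : %.1f%% (mean over %d subjects)\n",
              x$by_subject_mean, length(x$by_subject_fit)))
  invisible(x)
}

#' Attraction-probability curves by condition
#'
#' Evaluates the logistic attraction probability at the posterior-mean
#' stimuli coefficients over a grid of latent-state values, one curve per
#' factor level; when the covariate is active, curves are drawn at its
#' lowest, median, and highest observed values.
#'
#' @param fit an `mh_draws` object.
#' @param design a [design_spec()] (defaults to the one stored in `fit`).
#' @param z_grid latent-state grid; default `seq(-6, 6, by = 0.1)`.
#' @return A data frame with columns `level`, `x_label`, `x_value`, `z`,
#'   `pi`.
#' @export
attraction_curves <- function(fit, design = fit$design,
                              z_grid = seq(-6, 6, by = 0.1)) {
  pool <- pooled_draws(fit)
  p <- theta_to_params(colMeans(pool), design, fit$base, fit$fix_kappa)
  has_x <- any(c("covariate", "interaction") %in% design$active)
  x_reps <- if (has_x)
    c(low = min(design$x), middle = median(design$x),
      high = max(design$x)) else c(none = 0)
  out <- list()
  for (k in seq_len(design$K)) {
    for (xl in names(x_reps)) {
      beta_k <- 0
      if ("categorical" %in% design$active) beta_k <- p$gamma[k]
      if (has_x) {
        slope <- 0
        if ("covariate" %in% design$active) slope <- slope + p$eta
        if ("interaction" %in% design$active) slope <- slope + p$delta[k]
        beta_k <- beta_k + x_reps[[xl]] * slope
      }
      out[[length(out) + 1]] <- data.frame(
        level = design$level_labels[k], x_label = xl,
        x_value = unname(x_reps[[xl]]), z = z_grid,
        pi = attraction_prob(beta_k, z_grid, p$sign_convention))
    }
  }
  do.call(rbind, out)
}

#' Windowed attraction statistic
#'
#' The normalized discrete approximation of the integral of an
#' attraction-probability curve over a window of normalized process time:
#' the arithmetic mean of the curve over the window's step indices
#' (inclusive).
#'
#' @param pi_curve numeric vector of attraction probabilities over steps
#'   0..N.
#' @param window integer length-2: first and last step index (0-based,
#'   inclusive); e.g. `c(30, 50)` for the 30-50% window when N = 100.
#' @return A list with `window` and `p_delta`.
#' @export
window_statistic <- function(pi_curve, window) {
  stopifnot(length(window) == 2)
  window <- as.integer(round(window))
  if (window[1] > window[2]) stop("empty window")
  if (window[1] < 0 || window[2] > length(pi_curve) - 1)
    stop("window outside the curve support [0, ",
         length(pi_curve) - 1, "]")
  idx <- (window[1]:window[2]) + 1L
  list(window = window, p_delta = mean(pi_curve[idx]))
}

#' Cluster latent movement profiles
#'
#' Groups subjects by the functional similarity of their posterior-mean
#' smoothed latent paths: agglomerative (Ward) clustering on the
#' Euclidean distance between paths, optionally pre-smoothed by a 5-point
#' moving average. With `k = "auto"` the number of clusters is chosen in
#' 2..min(8, I - 1) by maximum mean silhouette width.
#'
#' @param paths numeric I x (N + 1) matrix of per-subject latent paths
#'   (e.g. `fit$latent_summaries`).
#' @param k integer number of clusters, or `"auto"`.
#' @param smooth logical: apply the 5-point moving average first.
#' @return An object of class `profile_clusters`: `assignments` (named
#'   integer vector), `k`, `silhouette` (mean width; NA when k = 1).
#' @export
cluster_profiles <- function(paths, k = "auto", smooth = TRUE) {
  paths <- as.matrix(paths)
  I <- nrow(paths)
  if (I < 2) stop("need at least 2 subjects to cluster")
  if (is.numeric(k) && k > I) stop("k cannot exceed the number of subjects")
  if (smooth && ncol(paths) >= 5) {
    kern <- rep(1 / 5, 5)
    paths <- t(apply(paths, 1, function(p)
      stats::filter(p, kern, sides = 2) |>
        (\(f) { f[is.na(f)] <- p[is.na(f)]; as.numeric(f) })()))
  }
  dd <- dist(paths)
  if (max(dd) < 1e-12) {
    warning("all profiles identical; reporting a single cluster")
    return(structure(list(assignments = setNames(rep(1L, I),
                                                 rownames(paths)),
                          k = 1L, silhouette = NA_real_),
                     class = "profile_clusters"))
  }
  hc <- hclust(dd, method = "ward.D2")
  sil_width <- function(cl) {
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, dd)[, "sil_width"])
  }
  if (identical(k, "auto")) {
    ks <- 2:min(8, I - 1)
    sw <- vapply(ks, function(kk) sil_width(cutree(hc, kk)), numeric(1))
    k <- ks[which.max(sw)]
  }
  cl <- cutree(hc, k)
  structure(list(assignments = setNames(as.integer(cl), rownames(paths)),
                 k = as.integer(k), silhouette = sil_width(cl)),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("Latent-profile clusters: k =", x$k,
      if (!is.na(x$silhouette))
        paste0("(mean silhouette ", round(x$silhouette, 3), ")"), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}
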