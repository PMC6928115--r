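#' Screen geometry of a mouse-tracking experiment
#'
#' Describes the recording surface: the horizontal and vertical screen
#' extent and the position of the start button. Trajectories are rescaled
#' relative to this geometry so that the start maps to (0, 0), the
#' horizontal extent to \[-1, 1\] and the vertical extent to \[0, 1\].
#'
#' @param xlim numeric length-2, horizontal screen extent (screen units).
#' @param ylim numeric length-2, vertical screen extent; `ylim[1]` is the
#'   bottom of the screen where movements start.
#' @param start numeric length-2, start-button position. Defaults to the
#'   bottom-center of the screen.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(c(0, 1920), c(0, 1080))
#' @export
screen_geometry <- function(xlim, ylim, start = c(mean(xlim), ylim[1])) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, length(start) == 2)
  if (diff(xlim) <= 0 || diff(ylim) <= 0)
    stop("screen extent must be positive in both directions")
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 start = as.numeric(start)),
            class = "screen_geometry")
}

#' Rescale a raw cursor trajectory to the normalized movement plane
#'
#' Translates a trajectory so its first sample sits at the origin and
#' linearly rescales coordinates so that the horizontal half-width of the
#' screen maps to 1 and the vertical extent maps to 1. After rescaling,
#' x lies in \[-1, 1\] (negative toward the distractor side, positive
#' toward the target side) and y in \[0, 1\].
#'
#' @param xy two-column matrix or data frame of (x, y) samples, temporally
#'   ordered.
#' @param geometry a [screen_geometry()] object.
#' @return A numeric matrix with columns `x`, `y`, same number of rows.
#' @examples
#' geom <- screen_geometry(c(0, 2), c(0, 1))
#' rescale_trajectory(cbind(c(1, 2), c(0, 1)), geom)
#' @export
rescale_trajectory <- function(xy, geometry) {
  if (!inherits(geometry, "screen_geometry"))
    stop("`geometry` must be a screen_geometry object")
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  if (nrow(xy) < 2) stop("degenerate trajectory: fewer than 2 samples")
  if (!all(is.finite(xy))) stop("non-finite coordinates in trajectory")
  half_w <- diff(geometry$xlim) / 2
  height <- diff(geometry$ylim)
  out <- cbind(x = (xy[, 1] - xy[1, 1]) / half_w,
               y = (xy[, 2] - xy[1, 2]) / height)
  out
}

#' Time-normalize a trajectory to a fixed number of steps
#'
#' Resamples a trajectory at `n_steps` equally spaced positions along the
#' cumulative sample index (0% to 100% of the recorded samples) by linear
#' interpolation of x and y separately. Endpoints are preserved exactly;
#' the operation is idempotent on its own output.
#'
#' @param xy two-column matrix of (x, y) samples.
#' @param n_steps integer, number of output samples (the model's N + 1);
#'   default 101.
#' @return An `n_steps` x 2 matrix with columns `x`, `y`.
#' @examples
#' time_normalize(cbind(c(0, 1), c(0, 1)), n_steps = 3)
#' @export
time_normalize <- function(xy, n_steps = 101) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  if (nrow(xy) < 2) stop("degenerate trajectory: fewer than 2 samples")
  if (!all(is.finite(xy))) stop("non-finite coordinates in trajectory")
  if (n_steps < 2) stop("n_steps must be at least 2")
  s <- seq(0, nrow(xy) - 1, length.out = n_steps)
  idx <- seq_len(nrow(xy)) - 1
  cbind(x = approx(idx, xy[, 1], xout = s)$y,
        y = approx(idx, xy[, 2], xout = s)$y)
}

#' Convert a normalized trajectory to movement angles
#'
#' Projects each (x, y) sample onto its movement direction through the
#' four-quadrant inverse tangent and folds the result into \[0, pi\] by
#' absolute value, so that angles near pi point toward the distractor-side
#' label (top-left) and angles near 0 toward the target side; small
#' downward excursions (y < 0) reflect into the upper half-plane. The
#' origin (0, 0) — in particular the start sample — carries no directional
#' information and is assigned the neutral angle pi/2.
#'
#' @param xy two-column matrix of normalized (x, y) samples.
#' @return Numeric vector of angles in \[0, pi\], one per sample.
#' @examples
#' to_angles(rbind(c(0, 0), c(1, 1), c(-1, 1)))  # pi/2, pi/4, 3*pi/4
#' @export
to_angles <- function(xy) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  ang <- abs(atan2(xy[, 2], xy[, 1]))
  ang[xy[, 1] == 0 & xy[, 2] == 0] <- pi / 2
  ang
}

#' Assemble per-trial angle sequences into an angle dataset
#'
#' @param angles a long data frame with columns `subject`, `trial`, `step`,
#'   `angle` (step starting at 0), or a named list of numeric vectors; all
#'   (subject, trial) cells must be present with a common length.
#' @return An [angle_dataset()] of dimension I x J x (N + 1).
#' @export
assemble_dataset <- function(angles) {
  df <- as.data.frame(angles)
  need <- c("subject", "trial", "step", "angle")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  subjects <- unique(df$subject)
  trials <- unique(df$trial)
  lens <- tapply(df$step, list(df$subject, df$trial), length)
  if (anyNA(lens)) {
    miss <- which(is.na(lens), arr.ind = TRUE)
    cells <- paste0("(", rownames(lens)[miss[, 1]], ", ",
                    colnames(lens)[miss[, 2]], ")")
    stop("missing (subject, trial) cells: ", paste(cells, collapse = " "))
  }
  if (length(unique(as.vector(lens))) != 1)
    stop("length mismatch: angle sequences differ across cells")
  n1 <- as.vector(lens)[1]
  arr <- array(NA_real_, dim = c(length(subjects), length(trials), n1))
  df <- df[order(match(df$subject, subjects), match(df$trial, trials),
                 df$step), ]
  arr[] <- aperm(array(df$angle, dim = c(n1, length(trials),
                                         length(subjects))), c(3, 2, 1))
  angle_dataset(arr, subject_ids = subjects, trial_ids = trials)
}

#' Angle dataset: the model's native input
#'
#' A dense I (subjects) x J (trials) x (N + 1) (time steps) array of
#' movement angles in \[0, pi\], the likelihood input of the state-space
#' model.
#'
#' @param angles numeric array of dimension I x J x (N + 1) with values in
#'   \[0, pi\].
#' @param subject_ids,trial_ids identifiers; default `1:I`, `1:J`.
#' @return An object of class `angle_dataset` (a numeric array with
#'   `subject_ids` and `trial_ids` attributes).
#' @export
angle_dataset <- function(angles, subject_ids = NULL, trial_ids = NULL) {
  if (length(dim(angles)) != 3)
    stop("`angles` must be a 3-dimensional array (subjects x trials x steps)")
  if (anyNA(angles)) stop("angle dataset contains missing cells")
  if (any(angles < 0 | angles > pi))
    stop("angles must lie in [0, pi]")
  if (is.null(subject_ids)) subject_ids <- seq_len(dim(angles)[1])
  if (is.null(trial_ids)) trial_ids <- seq_len(dim(angles)[2])
  stopifnot(length(subject_ids) == dim(angles)[1],
            length(trial_ids) == dim(angles)[2])
  structure(unclass(angles), subject_ids = subject_ids,
            trial_ids = trial_ids, class = "angle_dataset")
}

#' @export
print.angle_dataset <- function(x, ...) {
  d <- dim(x)
  cat("Angle dataset:", d[1], "subjects x", d[2], "trials x", d[3],
      "time steps\n")
  cat("  angle range: [", round(min(x), 3), ",", round(max(x), 3), "] rad\n")
  invisible(x)
}

#' Read raw trajectories and convert them to an angle dataset
#'
#' Reads a delimited trajectory table (columns `subject,trial,sample,x,y`,
#' header required), rescales each trajectory to the normalized movement
#' plane, time-normalizes it to `n_steps` samples, converts to movement
#' angles, and assembles the dense angle array.
#'
#' @param path path to the trajectory file (CSV).
#' @param geometry a [screen_geometry()] object.
#' @param n_steps number of normalized time steps (N + 1); default 101.
#' @return An [angle_dataset()].
#' @export
read_trajectories <- function(path, geometry, n_steps = 101) {
  df <- read.csv(path)
  need <- c("subject", "trial", "sample", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns: ", paste(need, collapse = ","))
  preprocess_trajectories(df, geometry, n_steps)
}

#' Preprocess a long trajectory table into an angle dataset
#'
#' @param df data frame with columns `subject`, `trial`, `sample`, `x`, `y`.
#' @inheritParams read_trajectories
#' @return An [angle_dataset()].
#' @export
preprocess_trajectories <- function(df, geometry, n_steps = 101) {
  sp <- split(df, list(df$subject, df$trial), drop = TRUE)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$sample), ]
    xy <- time_normalize(rescale_trajectory(cbind(d$x, d$y), geometry),
                         n_steps)
    data.frame(subject = d$subject[1], trial = d$trial[1],
               step = seq_len(n_steps) - 1, angle = to_angles(xy))
  })
  assemble_dataset(do.call(rbind, rows))
}

#' Write / read a cached angle file
#'
#' Plain-text cache of an angle dataset, columns
#' `subject,trial,step,angle_rad`.
#'
#' @param y an [angle_dataset()].
#' @param path file path.
#' @return `read_angles` returns an [angle_dataset()]; `write_angles`
#'   returns `path` invisibly.
#' @export
write_angles <- function(y, path) {
  d <- dim(y)
  df <- data.frame(
    subject = rep(attr(y, "subject_ids"), times = d[2] * d[3]),
    trial = rep(rep(attr(y, "trial_ids"), each = d[1]), times = d[3]),
    step = rep(seq_len(d[3]) - 1, each = d[1] * d[2]),
    angle_rad = as.vector(unclass(y)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  df <- read.csv(path)
  names(df)[names(df) == "angle_rad"] <- "angle"
  assemble_dataset(df)
}
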