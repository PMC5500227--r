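#' Time-averaged mean square displacement of one trajectory
#'
#' Discrete estimator of the sliding time average: for lag index k the mean
#' of |r(i+k) - r(i)|^2 over all N - k overlapping windows, converted to
#' seconds/um^2.
#'
#' @param traj a [trajectory()] with at least 2 points.
#' @param max_lag largest lag in seconds; must be smaller than the
#'   trajectory duration T. `NULL` (default) uses all available lags.
#' @return An `msd_curve`: lags (s), values (um^2), `spread` (NA for a
#'   single trajectory) and `n_contributing` (number of windows per lag).
#' @export
ta_msd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$positions)
  if (n < 2) stop("too-short: trajectory has fewer than 2 points", call. = FALSE)
  T_total <- traj$times[n] - traj$times[1]
  max_lag <- max_lag %||% T_total
  if (max_lag > T_total * (1 + 1e-9))
    stop("invalid-lag: max_lag must not exceed the trajectory duration", call. = FALSE)
  kmax <- min(n - 1L, floor(max_lag / traj$dt + 1e-9))
  if (kmax < 1) stop("invalid-lag: max_lag shorter than one frame", call. = FALSE)
  x <- traj$positions[, 1]; y <- traj$positions[, 2]
  vals <- numeric(kmax); nwin <- integer(kmax)
  for (k in seq_len(kmax)) {
    i <- seq_len(n - k)
    vals[k] <- mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
    nwin[k] <- n - k
  }
  structure(list(lags = seq_len(kmax) * traj$dt, values = vals,
                 spread = rep(NA_real_, kmax), n_contributing = nwin),
            class = "msd_curve")
}

#' Ensemble-averaged time-averaged MSD
#'
#' Per-lag mean of the per-trajectory time-averaged MSDs, each trajectory
#' weighted equally; `spread` is the per-lag standard deviation across
#' trajectories and `n_contributing` the number of trajectories long enough
#' to contribute at that lag.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param max_lag largest lag in seconds (`NULL`: all lags of the longest
#'   trajectory).
#' @return An `msd_curve`.
#' @export
ensemble_ta_msd <- function(ensemble, max_lag = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (!length(ensemble$trajectories)) stop("empty-input", call. = FALSE)
  dt <- ensemble$frame_interval
  xy <- ensemble_xy(ensemble)
  if (!is.null(xy)) {
    n <- nrow(xy$x)
    T_total <- (n - 1) * dt
    kmax <- min(n - 1L, floor((max_lag %||% T_total) / dt + 1e-9))
    if (kmax < 1) stop("invalid-lag", call. = FALSE)
    vals <- numeric(kmax); spr <- numeric(kmax)
    for (k in seq_len(kmax)) {
      i <- seq_len(n - k)
      d2 <- (xy$x[i + k, , drop = FALSE] - xy$x[i, , drop = FALSE])^2 +
            (xy$y[i + k, , drop = FALSE] - xy$y[i, , drop = FALSE])^2
      per_traj <- colMeans(d2)
      vals[k] <- mean(per_traj)
      spr[k] <- sd(per_traj)
    }
    return(structure(list(lags = seq_len(kmax) * dt, values = vals, spread = spr,
                          n_contributing = rep(ncol(xy$x), kmax)),
                     class = "msd_curve"))
  }
  curves <- lapply(ensemble$trajectories, ta_msd, max_lag = max_lag)
  kmax <- max(vapply(curves, function(cu) length(cu$lags), integer(1)))
  acc <- matrix(NA_real_, kmax, length(curves))
  for (j in seq_along(curves))
    acc[seq_along(curves[[j]]$values), j] <- curves[[j]]$values
  nc <- rowSums(!is.na(acc))
  structure(list(lags = seq_len(kmax) * dt,
                 values = rowMeans(acc, na.rm = TRUE),
                 spread = apply(acc, 1, sd, na.rm = TRUE),
                 n_contributing = nc),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat("<msd_curve>", length(x$lags), "lags,",
      signif(x$lags[1], 3), "-", signif(x$lags[length(x$lags)], 3), "s\n")
  invisible(x)
}

#' Convert an MSD curve to a data frame
#' @param x an `msd_curve`.
#' @param ... unused.
#' @export
as.data.frame.msd_curve <- function(x, ...) {
  data.frame(lag_s = x$lags, msd_um2 = x$values, sd_um2 = x$spread,
             n = x$n_contributing)
}

msd_fit_window <- function(msd, fit_range) {
  if (is.null(fit_range)) {
    dt <- msd$lags[1]
    fit_range <- c(2 * dt, min(1, msd$lags[length(msd$lags)] / 4))
    if (fit_range[2] <= fit_range[1]) fit_range <- range(msd$lags)
  }
  sel <- which(msd$lags >= fit_range[1] - 1e-12 & msd$lags <= fit_range[2] + 1e-12)
  list(sel = sel, fit_range = fit_range)
}

#' Fit the anomalous exponent of an MSD curve
#'
#' Unweighted least-squares straight line of log(MSD) on log(lag) inside
#' `fit_range`; the anomalous exponent alpha is the slope. alpha < 1
#' indicates subdiffusion, alpha = 1 normal diffusion.
#'
#' @param msd an `msd_curve`.
#' @param fit_range numeric length-2, seconds; default spans 2 frames to
#'   min(1 s, T/4).
#' @return A `power_law_fit` with `exponent`, `prefactor` (um^2/s^alpha),
#'   `fit_range` and `r_squared`.
#' @export
fit_anomalous_exponent <- function(msd, fit_range = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  w <- msd_fit_window(msd, fit_range)
  if (length(w$sel) < 3) stop("too-few-points: need >= 3 lags in fit_range", call. = FALSE)
  v <- msd$values[w$sel]
  if (any(v <= 0)) stop("invalid-data: nonpositive MSD value in fit range", call. = FALSE)
  lx <- log(msd$lags[w$sel]); ly <- log(v)
  fit <- lm(ly ~ lx)
  r2 <- if (sd(ly) == 0) 1 else cor(lx, ly)^2
  structure(list(exponent = unname(coef(fit)[2]),
                 prefactor = exp(unname(coef(fit)[1])),
                 fit_range = w$fit_range,
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> MSD ~ %.4g * lag^%.4g  (R2 = %.4f)\n",
              x$prefactor, x$exponent, x$r_squared))
  invisible(x)
}

#' Fit a diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of MSD on lag; in 2D the slope equals 4 D.
#'
#' @inheritParams fit_anomalous_exponent
#' @return A `diffusion_fit` with `diffusivity` (um^2/s), `intercept` (um^2)
#'   and `fit_range`.
#' @export
fit_diffusivity <- function(msd, fit_range = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  w <- msd_fit_window(msd, fit_range)
  if (length(w$sel) < 3) stop("too-few-points: need >= 3 lags in fit_range", call. = FALSE)
  fit <- lm(msd$values[w$sel] ~ msd$lags[w$sel])
  structure(list(diffusivity = unname(coef(fit)[2]) / 4,
                 intercept = unname(coef(fit)[1]),
                 fit_range = w$fit_range),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um2/s (intercept %.3g um2)\n",
              x$diffusivity, x$intercept))
  invisible(x)
}
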