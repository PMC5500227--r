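#' Single-particle trajectory
#'
#' A trajectory is a time-ordered sequence of 2D positions of one particle,
#' sampled on a uniform time grid. Positions are in micrometres, times in
#' seconds.
#'
#' @param track_id identifier (coerced to character).
#' @param times numeric vector of time stamps in seconds; strictly increasing
#'   and uniformly spaced.
#' @param positions n x 2 numeric matrix of (x, y) positions in micrometres,
#'   one row per time stamp.
#' @return An object of class `trajectory` with fields `track_id`, `times`,
#'   `positions` and the frame interval `dt` (seconds).
#' @export
trajectory <- function(track_id, times, positions) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 2)
    stop("positions must be an n x 2 matrix", call. = FALSE)
  n <- length(times)
  if (n != nrow(positions))
    stop("times and positions must have the same length", call. = FALSE)
  if (n < 1) stop("a trajectory needs at least one point", call. = FALSE)
  dt <- NA_real_
  if (n > 1) {
    d <- diff(times)
    if (any(d <= 0))
      stop("times must be strictly increasing (track ", track_id, ")", call. = FALSE)
    if (max(d) - min(d) > 1e-9 * max(d))
      stop("times must be uniformly spaced (track ", track_id, ")", call. = FALSE)
    dt <- mean(d)
  }
  structure(
    list(track_id = as.character(track_id), times = as.numeric(times),
         positions = unname(positions), dt = dt),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> id:", x$track_id, " points:", nrow(x$positions),
      " dt:", signif(x$dt, 4), "s\n")
  invisible(x)
}

#' Ensemble of trajectories sharing one frame interval
#'
#' @param trajectories list of [trajectory()] objects.
#' @param frame_interval frame interval in seconds; defaults to the common
#'   `dt` of the members (0.02 s, i.e. 50 frames/s, for all built-in
#'   simulators).
#' @return Object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, frame_interval = NULL) {
  if (!length(trajectories)) stop("empty ensemble", call. = FALSE)
  dts <- vapply(trajectories, function(tr) tr$dt, numeric(1))
  dts <- dts[!is.na(dts)]
  if (length(dts)) {
    if (max(dts) - min(dts) > 1e-9 * max(dts))
      stop("all trajectories in an ensemble must share dt", call. = FALSE)
    frame_interval <- frame_interval %||% dts[1]
  }
  structure(list(trajectories = trajectories,
                 frame_interval = frame_interval %||% 0.02),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  np <- vapply(x$trajectories, function(tr) nrow(tr$positions), integer(1))
  cat("<trajectory_ensemble>", length(x$trajectories), "trajectories,",
      "frame interval", signif(x$frame_interval, 4), "s, lengths",
      min(np), "-", max(np), "\n")
  invisible(x)
}

#' @export
length.trajectory_ensemble <- function(x) length(x$trajectories)

#' Read trajectories from CSV
#'
#' The schema is `track_id,frame,t_s,x_um,y_um` with a header row; `frame` is
#' 0-based. Malformed tables fail with an error naming the offending column
#' or track.
#'
#' @param path path to a CSV file.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema-error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!complete.cases(df[required]))
  if (length(bad))
    stop("data-error: malformed rows (NA values) at line(s): ",
         paste(head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  trajs <- lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (anyDuplicated(d$frame))
      stop("data-error: duplicated frame in track ", d$track_id[1], call. = FALSE)
    if (is.unsorted(d$t_s, strictly = TRUE))
      stop("data-error: non-monotone times in track ", d$track_id[1], call. = FALSE)
    trajectory(d$track_id[1], d$t_s, cbind(d$x_um, d$y_um))
  })
  trajectory_ensemble(unname(trajs))
}

#' Write trajectories to CSV
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  dt <- ensemble$frame_interval
  rows <- lapply(ensemble$trajectories, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = as.integer(round(tr$times / dt)),
               t_s = tr$times, x_um = tr$positions[, 1], y_um = tr$positions[, 2])
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: stack an equal-length ensemble into n_frames x n_traj matrices
ensemble_xy <- function(ensemble) {
  np <- vapply(ensemble$trajectories, function(tr) nrow(tr$positions), integer(1))
  if (length(unique(np)) != 1) return(NULL)
  list(x = vapply(ensemble$trajectories, function(tr) tr$positions[, 1], numeric(np[1])),
       y = vapply(ensemble$trajectories, function(tr) tr$positions[, 2], numeric(np[1])))
}
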