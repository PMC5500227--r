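#' Build a random obstacle lattice
#'
#' Places exactly `round(obstacle_fraction * side^2)` immobile obstacles
#' uniformly at random (without replacement) on a `side` x `side` square
#' lattice. The lattice is periodic for the walk dynamics; walks report
#' unwrapped coordinates so that MSDs are free of wrap-around artifacts.
#'
#' @param side lattice side length in sites.
#' @param obstacle_fraction fraction of occupied (blocking) sites, in \[0, 1).
#' @param lattice_constant physical site spacing in micrometres. The default
#'   0.01 um (10 nm) is the scale of an individual actin filament, the
#'   molecular obstacle the lattice emulates.
#' @param seed integer seed.
#' @return Object of class `lattice_world` with the boolean occupancy grid
#'   (`TRUE` = obstacle).
#' @export
build_obstacle_lattice <- function(side, obstacle_fraction, lattice_constant = 0.01,
                                   seed = 1) {
  if (!is.finite(obstacle_fraction) || obstacle_fraction < 0 || obstacle_fraction >= 1)
    stop("invalid-parameter: obstacle_fraction must lie in [0, 1)", call. = FALSE)
  if (side < 2) stop("invalid-parameter: side must be >= 2", call. = FALSE)
  n_obs <- round(obstacle_fraction * side^2)
  set.seed(as.integer(seed))
  occ <- matrix(FALSE, side, side)
  if (n_obs > 0) occ[sample.int(side^2, n_obs)] <- TRUE
  structure(list(side = as.integer(side),
                 obstacle_fraction = obstacle_fraction,
                 occupancy = occ,
                 lattice_constant = lattice_constant,
                 boundary = "periodic",
                 seed = as.integer(seed)),
            class = "lattice_world")
}

#' @export
print.lattice_world <- function(x, ...) {
  cat("<lattice_world>", x$side, "x", x$side, "sites,",
      sum(x$occupancy), "obstacles (fraction", signif(mean(x$occupancy), 4), "),",
      "a =", x$lattice_constant, "um\n")
  invisible(x)
}

# 4-connected vacant-phase clusters (non-periodic); labels of obstacles are 0
lattice_clusters <- function(world) {
  cpp_label4(!world$occupancy)
}

#' Simulate obstructed diffusion on an obstacle lattice
#'
#' Blind-ant dynamics: at every microscopic step one of the 4 neighbours is
#' drawn uniformly, and the move is taken iff the target site is vacant
#' (time advances either way). Site percolation: near the percolation
#' threshold the vacant phase is fractal and the walk is subdiffusive. The
#' walk is recorded once per camera frame; `steps_per_frame` microscopic
#' steps make up one frame, mirroring video-rate observation of a much
#' faster molecular-scale process (with the default lattice constant of
#' 10 nm and a vacant-lattice diffusion coefficient of 0.19 um^2/s, one
#' 20-ms frame corresponds to about 150 lattice steps).
#'
#' @param world a `lattice_world` from [build_obstacle_lattice()].
#' @param n_steps number of recorded frames per trajectory.
#' @param n_traj number of trajectories.
#' @param seed integer root seed (per-trajectory derived streams).
#' @param steps_per_frame microscopic lattice steps per recorded frame
#'   (default 1: every step is recorded).
#' @param dt frame interval in seconds.
#' @param start one of "vacant" (uniform over all vacant sites, the default:
#'   particles land anywhere) or "largest_cluster" (uniform over the largest
#'   4-connected vacant cluster, the scale-free reference structure).
#' @param ant "blind" (attempt-and-stay) or "myopic" (choose among vacant
#'   neighbours only).
#' @return A [trajectory_ensemble()]; positions in micrometres via the
#'   lattice constant, unwrapped across the periodic boundary.
#' @export
simulate_obstructed_walk <- function(world, n_steps, n_traj = 1, seed = 1,
                                     steps_per_frame = 1, dt = 0.02,
                                     start = c("vacant", "largest_cluster"),
                                     ant = c("blind", "myopic")) {
  stopifnot(inherits(world, "lattice_world"))
  start <- match.arg(start)
  ant <- match.arg(ant)
  vac <- which(!world$occupancy)
  if (!length(vac)) stop("no-vacant-site: lattice is fully occupied", call. = FALSE)
  if (start == "largest_cluster") {
    lab <- lattice_clusters(world)
    sizes <- tabulate(lab[lab > 0])
    vac <- which(lab == which.max(sizes))
  }
  side <- world$side
  a <- world$lattice_constant
  seeds <- split_seeds(seed, n_traj)
  times <- (0:n_steps) * dt
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    s0 <- vac[sample.int(length(vac), 1)]
    i0 <- (s0 - 1L) %% side          # 0-based row
    j0 <- (s0 - 1L) %/% side         # 0-based col
    path <- cpp_obstructed_walk(world$occupancy, i0, j0, n_steps,
                                as.integer(steps_per_frame), ant == "myopic")
    trajs[[i]] <- trajectory(sprintf("perc_%04d", i), times,
                             cbind(path[, 1] * a, path[, 2] * a))
  }
  trajectory_ensemble(trajs, frame_interval = dt)
}

#' Estimate the obstacle percolation threshold
#'
#' Monte-Carlo estimate of the obstacle fraction at which the vacant phase
#' stops forming a top-to-bottom 4-connected spanning cluster on a square
#' lattice. Each realization assigns every site an independent uniform
#' priority; obstacles at fraction f are the f quantile of priorities, so
#' spanning is monotone in f and the per-realization critical fraction is
#' found by bisection. The complement of the classical site-percolation
#' threshold (0.592746 for the vacant phase) is approximately 0.4073.
#'
#' @param side lattice side in sites (>= 8; use >= 64 for useful accuracy).
#' @param n_realizations number of independent lattices.
#' @param seed integer seed.
#' @param tol bisection tolerance on the fraction.
#' @return List with `threshold` (mean critical obstacle fraction),
#'   `se` (standard error), and the per-realization values.
#' @export
estimate_percolation_threshold <- function(side = 256, n_realizations = 200,
                                           seed = 1, tol = 1e-4) {
  if (side < 8) stop("invalid-parameter: side must be >= 8", call. = FALSE)
  seeds <- split_seeds(seed, n_realizations)
  crit <- numeric(n_realizations)
  for (r in seq_len(n_realizations)) {
    set.seed(seeds[r])
    pri <- runif(side * side)
    lo <- 0; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cpp_spans(pri < mid, side)) lo <- mid else hi <- mid
    }
    crit[r] <- (lo + hi) / 2
  }
  list(threshold = mean(crit), se = sd(crit) / sqrt(n_realizations),
       realizations = crit, side = side)
}
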