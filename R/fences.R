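#' Square grid of permeable fences
#'
#' The picket-fence model of hop diffusion: free diffusion inside square
#' compartments of side `compartment_side`, with a Bernoulli gate at every
#' fence crossing. A crossing attempt succeeds with probability
#' `hop_probability`; otherwise the step is reflected off the fence, which
#' preserves step-length statistics.
#'
#' @param compartment_side fence pitch in micrometres (> 0).
#' @param hop_probability probability that a step crossing a fence is let
#'   through, in \[0, 1\].
#' @param diffusivity intra-compartment diffusion coefficient in um^2/s.
#' @param dt frame interval in seconds.
#' @return Object of class `fence_world`.
#' @export
fence_world <- function(compartment_side, hop_probability, diffusivity = 0.19,
                        dt = 0.02) {
  if (!is.finite(compartment_side) || compartment_side <= 0)
    stop("invalid-parameter: compartment_side must be > 0", call. = FALSE)
  if (!is.finite(hop_probability) || hop_probability < 0 || hop_probability > 1)
    stop("invalid-parameter: hop_probability must lie in [0, 1]", call. = FALSE)
  if (!is.finite(diffusivity) || diffusivity < 0)
    stop("invalid-parameter: diffusivity must be >= 0", call. = FALSE)
  structure(list(compartment_side = compartment_side,
                 hop_probability = hop_probability,
                 diffusivity = diffusivity, dt = dt),
            class = "fence_world")
}

#' @export
print.fence_world <- function(x, ...) {
  cat("<fence_world> L =", x$compartment_side, "um, hop p =",
      x$hop_probability, ", D =", x$diffusivity, "um2/s\n")
  invisible(x)
}

#' Simulate hop diffusion across permeable fences
#'
#' Gaussian steps of per-axis variance `2 D dt` on a square fence grid. Each
#' fence line crossed by a step is tested independently in crossing order;
#' rejection reflects the offending coordinate about the fence. With
#' `hop_probability = 1` the walk is free Brownian motion; with 0 it is
#' confined to its starting compartment and the long-time MSD plateaus at
#' `compartment_side^2 / 3` (two independent uniform points in a square).
#'
#' Starting positions are uniform inside the compartment `[0, L]^2`, so the
#' confined walk is stationary from the first frame.
#'
#' @param world a [fence_world()].
#' @param n_steps steps per trajectory.
#' @param n_traj number of trajectories.
#' @param seed integer root seed (per-trajectory derived streams).
#' @return A [trajectory_ensemble()].
#' @export
simulate_fenced_diffusion <- function(world, n_steps, n_traj = 1, seed = 1) {
  stopifnot(inherits(world, "fence_world"))
  L <- world$compartment_side
  sigma <- sqrt(2 * world$diffusivity * world$dt)
  seeds <- split_seeds(seed, n_traj)
  times <- (0:n_steps) * world$dt
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    x0 <- runif(1, 0, L); y0 <- runif(1, 0, L)
    path <- cpp_fenced_walk(n_steps, L, world$hop_probability, sigma, x0, y0)
    trajs[[i]] <- trajectory(sprintf("hop_%04d", i), times, path)
  }
  trajectory_ensemble(trajs, frame_interval = world$dt)
}
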