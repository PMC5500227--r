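#' Autocovariance of fractional Gaussian noise
#'
#' gamma(k) = (sigma^2/2) (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}), the exact
#' increment autocovariance of fractional Brownian motion with Hurst
#' exponent H.
#'
#' @param k integer lag(s).
#' @param hurst Hurst exponent in (0, 1).
#' @param sigma2 increment variance (value at lag 0).
#' @return Numeric vector of autocovariances.
#' @export
fgn_autocovariance <- function(k, hurst, sigma2 = 1) {
  h2 <- 2 * hurst
  sigma2 / 2 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

# Davies-Harte circulant embedding eigenvalues for fGn of length n;
# NULL if the embedding is not nonnegative definite.
dh_eigenvalues <- function(n, hurst) {
  g <- fgn_autocovariance(0:n, hurst)
  circ <- c(g, rev(g[2:n]))           # length 2n
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(abs(lam))) return(NULL)
  pmax(lam, 0)
}

# Exact fGn sample paths via circulant embedding. Returns n x n_traj matrix
# of increments with unit variance. Consumes 2 * 2n normals per trajectory
# from the current RNG stream.
dh_fgn <- function(n, hurst, n_traj, lam) {
  m <- 2L * n
  z1 <- matrix(rnorm(m * n_traj), m, n_traj)
  z2 <- matrix(rnorm(m * n_traj), m, n_traj)
  v <- matrix(0 + 0i, m, n_traj)
  v[1, ] <- sqrt(lam[1]) * z1[1, ]
  v[n + 1, ] <- sqrt(lam[n + 1]) * z1[n + 1, ]
  k <- 2:n
  v[k, ] <- sqrt(lam[k] / 2) * (z1[k, ] + 1i * z2[k, ])
  v[m - k + 2, ] <- Conj(v[k, ])
  Re(mvfft(v))[1:n, , drop = FALSE] / sqrt(m)
}

# Hosking (Durbin-Levinson) sequential sampling of fGn; exact but O(n^2).
# Fallback for the (theoretically absent) case of an indefinite embedding.
hosking_fgn <- function(n, hurst, n_traj) {
  g <- fgn_autocovariance(0:n, hurst)
  x <- matrix(0, n, n_traj)
  x[1, ] <- rnorm(n_traj) * sqrt(g[1])
  if (n == 1) return(x)
  phi <- numeric(n)
  v <- g[1]
  for (i in 1:(n - 1)) {
    if (i == 1) {
      phi_new <- g[2] / g[1]
      phi[1] <- phi_new
    } else {
      phi_new <- (g[i + 1] - sum(phi[1:(i - 1)] * g[i:2])) / v
      phi[1:(i - 1)] <- phi[1:(i - 1)] - phi_new * phi[(i - 1):1]
      phi[i] <- phi_new
    }
    v <- v * (1 - phi_new^2)
    mu <- crossprod(x[i:1, , drop = FALSE], phi[1:i])[, 1]
    x[i + 1, ] <- mu + rnorm(n_traj) * sqrt(v)
  }
  x
}

#' Simulate fractional Brownian motion trajectories
#'
#' x and y are independent fBM paths whose increments have the exact fGn
#' autocovariance [fgn_autocovariance()]. Synthesis uses Davies-Harte
#' circulant embedding, with a Hosking (Durbin-Levinson) fallback when the
#' embedding is not nonnegative definite. Subdiffusive for `hurst` < 0.5;
#' the ensemble MSD grows as `2 * step_scale^2 * k^(2 hurst)` at lag k
#' frames, i.e. the anomalous exponent equals `2 * hurst`.
#'
#' @param hurst Hurst exponent, in (0, 1).
#' @param n_steps number of increments per trajectory (>= 1).
#' @param dt frame interval in seconds (default 0.02 s = 50 frames/s).
#' @param step_scale micrometres per unit step: standard deviation of a
#'   single-frame increment per axis.
#' @param n_traj number of trajectories.
#' @param seed integer root seed; each trajectory consumes its own derived
#'   stream, so results do not depend on batching.
#' @return A [trajectory_ensemble()] of `n_traj` trajectories with
#'   `n_steps + 1` points starting at the origin.
#' @export
simulate_fbm <- function(hurst, n_steps, dt = 0.02, step_scale = 0.1,
                         n_traj = 1, seed = 1) {
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("invalid-parameter: hurst must lie in (0, 1)", call. = FALSE)
  if (n_steps < 1) stop("invalid-parameter: n_steps must be >= 1", call. = FALSE)
  lam <- if (n_steps >= 2) dh_eigenvalues(n_steps, hurst) else NULL
  seeds <- split_seeds(seed, n_traj)
  times <- (0:n_steps) * dt
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    inc <- if (is.null(lam)) hosking_fgn(n_steps, hurst, 2)
           else dh_fgn(n_steps, hurst, 2, lam)
    pos <- apply(inc * step_scale, 2, cumsum)
    trajs[[i]] <- trajectory(sprintf("fbm_%04d", i), times,
                             rbind(c(0, 0), pos))
  }
  trajectory_ensemble(trajs, frame_interval = dt)
}

#' Simulate free Brownian motion trajectories
#'
#' Independent Gaussian increments per axis with variance `2 * diffusivity *
#' dt`, the 2D law MSD = 4 D t.
#'
#' @param diffusivity diffusion coefficient in um^2/s (>= 0).
#' @param dt frame interval in seconds.
#' @param n_steps increments per trajectory.
#' @param n_traj number of trajectories.
#' @param seed integer root seed (per-trajectory derived streams).
#' @return A [trajectory_ensemble()].
#' @export
simulate_brownian <- function(diffusivity, dt = 0.02, n_steps = 100,
                              n_traj = 1, seed = 1) {
  if (!is.finite(diffusivity) || diffusivity < 0)
    stop("invalid-parameter: diffusivity must be >= 0", call. = FALSE)
  if (n_steps < 1) stop("invalid-parameter: n_steps must be >= 1", call. = FALSE)
  sdv <- sqrt(2 * diffusivity * dt)
  seeds <- split_seeds(seed, n_traj)
  times <- (0:n_steps) * dt
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    inc <- matrix(rnorm(2 * n_steps, sd = sdv), n_steps, 2)
    pos <- rbind(c(0, 0), apply(inc, 2, cumsum))
    trajs[[i]] <- trajectory(sprintf("bm_%04d", i), times, pos)
  }
  trajectory_ensemble(trajs, frame_interval = dt)
}
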