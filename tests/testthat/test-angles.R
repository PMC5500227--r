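test_that("turning angles match hand-computed geometry", {
  expect_equal(as.numeric(turning_angles(make_traj(c(0, 0, 1, 0, 2, 0)), 1)), 0)
  expect_equal(as.numeric(turning_angles(make_traj(c(0, 0, 1, 0, 0, 0)), 1)), 180)
  expect_equal(as.numeric(turning_angles(make_traj(c(0, 0, 1, 0, 1, 1)), 1)), 90)
  expect_error(turning_angles(make_traj(c(0, 0, 1, 0, 1, 1)), 1.5), "invalid-lag")
})

test_that("zero-length displacements are skipped and counted", {
  tr <- make_traj(c(0, 0, 0, 0, 1, 0, 2, 0))   # first displacement is zero
  a <- turning_angles(tr, 1)
  expect_equal(attr(a, "n_skipped"), 1L)
  expect_equal(as.numeric(a), 0)
})

test_that("angle densities integrate to one and live in [0, 180]", {
  ens <- simulate_fbm(0.3, 128, n_traj = 50, seed = 3)
  for (d in angle_distribution(ens, c(0.02, 0.1, 0.5))) {
    expect_lt(abs(sum(d$density) * 5 - 1), 1e-9)
    expect_true(all(d$density >= 0))
  }
  raw <- turning_angles(ens$trajectories[[1]], 0.02)
  expect_true(all(raw >= 0 & raw <= 180))
})

test_that("Brownian turning angles are uniform (chi-square over 36 bins)", {
  ens <- simulate_brownian(0.19, n_steps = 60, n_traj = 2000, seed = 14)
  d <- angle_distribution(ens, 0.02)[[1]]
  expect_gte(d$n_angles, 1e5)
  counts <- d$density * 5 * d$n_angles
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.001)
  # max per-bin deviation from the uniform density 1/180 per degree
  expect_lt(max(abs(d$density - 1 / 180)) / (1 / 180), 0.05)
})

test_that("subdiffusive fBM peaks in the terminal bin", {
  # the fBM angle density rises to a plateau near 180 degrees (terminal
  # 5-degree bins differ by only ~0.5%), so the mode check uses bins wide
  # enough for the edge bin to dominate the sampling noise
  ens <- simulate_fbm(0.3, 256, n_traj = 500, seed = 4)
  d <- angle_distribution(ens, 0.02, bin_width = 15)[[1]]
  expect_equal(which.max(d$density), 12L)
  expect_equal(as.numeric(angle_mode(d)), 180)
})

test_that("angle_mode tie-breaks toward 180 and flags the tie", {
  d <- structure(list(lag = 0.02, bin_edges = seq(0, 180, 5),
                      density = rep(1 / 180, 36), n_angles = 100L,
                      n_skipped = 0L), class = "angle_distribution")
  m <- angle_mode(d)
  expect_equal(as.numeric(m), 180)
  expect_true(attr(m, "tie"))
  rising <- d; rising$density <- seq_len(36) / sum(seq_len(36)) / 5
  expect_equal(as.numeric(angle_mode(rising)), 180)
})

test_that("lag-invariance statistic is a binned two-sample KS statistic", {
  mk <- function(dens) structure(list(lag = 1, bin_edges = seq(0, 180, 5),
                                      density = dens, n_angles = 1000L,
                                      n_skipped = 0L), class = "angle_distribution")
  u <- mk(rep(1 / 180, 36))
  expect_equal(lag_invariance_statistic(list(u, u)), 0)
  at0 <- mk(c(1 / 5, rep(0, 35)))
  at180 <- mk(c(rep(0, 35), 1 / 5))
  expect_equal(lag_invariance_statistic(list(at0, at180)), 1)
  bad <- mk(rep(1 / 180, 36)); bad$bin_edges <- seq(0, 180, 10)[1:37]
  expect_error(lag_invariance_statistic(list(u, bad)), "invalid-input")
})
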