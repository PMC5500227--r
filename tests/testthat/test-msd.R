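test_that("TA-MSD reproduces hand-computed values on a ballistic path", {
  tr <- make_traj(c(0, 0, 1, 0, 2, 0, 3, 0), dt = 1)
  msd <- ta_msd(tr)
  expect_equal(msd$values, c(1, 4, 9))
  expect_equal(msd$n_contributing, c(3L, 2L, 1L))
})

test_that("TA-MSD equals the naive double-loop oracle to 1e-12", {
  set.seed(31)
  for (rep in 1:50) {
    pos <- matrix(cumsum(rnorm(200)), 100, 2)
    tr <- trajectory("r", (0:99) * 0.02, pos)
    got <- ta_msd(tr)$values
    want <- naive_ta_msd(pos, 0.02)
    expect_lt(max(abs(got - want) / pmax(want, 1e-300)), 1e-12)
  }
})

test_that("degenerate TA-MSD inputs are handled", {
  still <- make_traj(rep(c(2, 3), 5), dt = 1)
  expect_true(all(ta_msd(still)$values == 0))
  expect_error(ta_msd(make_traj(c(0, 0), dt = 1)), "too-short")
  tr <- make_traj(c(0, 0, 1, 0, 2, 0), dt = 1)
  expect_error(ta_msd(tr, max_lag = 10), "invalid-lag")
})

test_that("ensemble TA-MSD averages per-trajectory curves with their spread", {
  tr <- make_traj(c(0, 0, 1, 0, 2, 0, 3, 0), dt = 1)
  same <- trajectory_ensemble(list(tr, tr, tr))
  m <- ensemble_ta_msd(same)
  expect_equal(m$values, c(1, 4, 9))
  expect_true(all(m$spread == 0))
  single <- ensemble_ta_msd(trajectory_ensemble(list(tr)))
  expect_equal(single$values, ta_msd(tr)$values)

  ens <- simulate_brownian(0.1, n_steps = 64, n_traj = 4000, seed = 17)
  msd <- ensemble_ta_msd(ens)
  slope <- fit_diffusivity(msd, fit_range = c(0.02, 0.4))$diffusivity * 4
  expect_lt(abs(slope - 0.4) / 0.4, 0.05)
})

test_that("mixed-length ensembles average over contributing trajectories", {
  t1 <- make_traj(c(0, 0, 1, 0, 2, 0), dt = 1)          # lags 1..2
  t2 <- make_traj(c(0, 0, 2, 0, 4, 0, 6, 0), dt = 1)    # lags 1..3
  m <- ensemble_ta_msd(trajectory_ensemble(list(t1, t2)))
  expect_equal(m$n_contributing, c(2L, 2L, 1L))
  expect_equal(m$values[1], mean(c(1, 4)))
})

test_that("anomalous-exponent fit is exact on exact power laws", {
  lags <- (1:50) * 0.02
  curve <- structure(list(lags = lags, values = 0.02 * lags^0.74,
                          spread = rep(0, 50), n_contributing = rep(10L, 50)),
                     class = "msd_curve")
  fit <- fit_anomalous_exponent(curve, c(0.02, 1))
  expect_equal(fit$exponent, 0.74, tolerance = 1e-12)
  expect_equal(fit$prefactor, 0.02, tolerance = 1e-10)

  lin <- structure(list(lags = lags, values = 0.5 * lags,
                        spread = rep(0, 50), n_contributing = rep(10L, 50)),
                   class = "msd_curve")
  expect_equal(fit_anomalous_exponent(lin, c(0.02, 1))$exponent, 1, tolerance = 1e-12)

  zero <- lin; zero$values[3] <- 0
  expect_error(fit_anomalous_exponent(zero, c(0.02, 1)), "invalid-data")
  expect_error(fit_anomalous_exponent(lin, c(0.02, 0.04)), "too-few-points")
})

test_that("diffusivity fit is slope/4 and exact on exact lines", {
  lags <- (1:50) * 0.02
  curve <- structure(list(lags = lags, values = 4 * 0.19 * lags,
                          spread = rep(0, 50), n_contributing = rep(10L, 50)),
                     class = "msd_curve")
  expect_equal(fit_diffusivity(curve, c(0.02, 1))$diffusivity, 0.19,
               tolerance = 1e-12)
  flat <- curve; flat$values <- rep(2, 50)
  expect_equal(fit_diffusivity(flat, c(0.02, 1))$diffusivity, 0)
})
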