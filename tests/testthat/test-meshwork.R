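test_that("fragmentation conserves area exactly and respects the split count", {
  m0 <- generate_fragmentation_meshwork(n_generations = 0, seed = 1)
  expect_equal(nrow(m0$compartments), 1L)
  expect_equal(m0$compartments$area_um2, 400)

  mseq <- generate_fragmentation_meshwork(n_generations = 25, seed = 2,
                                          scheme = "sequential")
  expect_equal(nrow(mseq$compartments), 26L)   # one split per generation
  expect_lt(abs(sum(mseq$compartments$area_um2) - 400) / 400, 1e-9)

  mgen <- generate_fragmentation_meshwork(n_generations = 8, seed = 3)
  expect_lt(abs(sum(mgen$compartments$area_um2) - 400) / 400, 1e-9)
  expect_true(all(mgen$compartments$area_um2 > 0))
  expect_true(all(mgen$compartments$perimeter_um > 0))
  expect_error(generate_fragmentation_meshwork(split_fraction_law = c(0, 2)),
               "invalid-parameter")
})

test_that("synchronous breakage yields log-normal areas (Kolmogorov limit)", {
  m <- generate_fragmentation_meshwork(n_generations = 11, seed = 1)
  expect_gt(nrow(m$compartments), 1500)
  fit <- fit_lognormal_areas(m$compartments$area_um2)
  expect_gt(fit$gof_p, 0.01)
})

test_that("log-area skewness shrinks as generations accumulate", {
  sk <- vapply(c(5, 15), function(g) {
    mean(vapply(1:3, function(s) {
      m <- generate_fragmentation_meshwork(n_generations = g, seed = s,
                                           min_area = 1e-9)
      abs(skewness(log(m$compartments$area_um2)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(sk[2], sk[1])
})

test_that("localization sampling reproduces the precision law and frame range", {
  mesh <- generate_fragmentation_meshwork(n_generations = 8, seed = 5)
  locs <- meshwork_to_localizations(mesh, linear_density = 100,
                                    precision_mean = 20, precision_sd = 8,
                                    n_frames = 100, seed = 6)
  expect_gt(nrow(locs), 1e4)
  expect_lt(abs(mean(locs$precision_nm) - 20), 1)
  expect_true(all(locs$frame >= 0 & locs$frame <= 99))
  fov <- attr(locs, "fov_nm")
  expect_true(all(locs$x_nm >= fov[1] & locs$x_nm <= fov[2]))
})

test_that("localization counts are proportional to fence length", {
  mesh <- grid_mesh(3, 3)
  lens <- sqrt((mesh$fences[, 3] - mesh$fences[, 1])^2 +
               (mesh$fences[, 4] - mesh$fences[, 2])^2)
  set.seed(1)
  counts <- vapply(1:30, function(s) {
    locs <- meshwork_to_localizations(mesh, linear_density = 200,
                                      precision_sd = 0.001, n_frames = 10,
                                      seed = s)
    nrow(locs)
  }, numeric(1))
  expected <- 200 * sum(lens)
  chi <- sum((counts - expected)^2 / expected)   # Poisson totals
  expect_gt(pchisq(chi, df = 30, lower.tail = FALSE), 0.01)
})

test_that("an empty meshwork cannot be imaged", {
  empty <- generate_fragmentation_meshwork(n_generations = 0, seed = 1,
                                           include_boundary = FALSE)
  expect_error(meshwork_to_localizations(empty), "empty-mesh")
})

test_that("impermeable meshwork walls confine tracks to their compartment", {
  mesh <- generate_fragmentation_meshwork(n_generations = 7, seed = 7)
  ens <- simulate_meshwork_confined_tracks(mesh, hop_probability = 0,
                                           n_steps = 300, n_traj = 20, seed = 8)
  rc <- attr(ens, "start_compartment")
  comp <- mesh$compartments
  for (i in seq_along(ens$trajectories)) {
    p <- ens$trajectories[[i]]$positions
    expect_true(all(p[, 1] >= comp$xmin[rc[i]] - 1e-7 &
                    p[, 1] <= comp$xmax[rc[i]] + 1e-7 &
                    p[, 2] >= comp$ymin[rc[i]] - 1e-7 &
                    p[, 2] <= comp$ymax[rc[i]] + 1e-7))
  }
})

test_that("fully permeable meshwork walls leave diffusion free", {
  mesh <- generate_fragmentation_meshwork(n_generations = 7, seed = 7,
                                          region = c(50, 50))
  ens <- simulate_meshwork_confined_tracks(mesh, hop_probability = 1,
                                           n_steps = 128, n_traj = 400, seed = 9)
  fit <- fit_anomalous_exponent(ensemble_ta_msd(ens, max_lag = 1),
                                fit_range = c(0.04, 1))
  expect_lt(abs(fit$exponent - 1), 0.03)
})

test_that("confined displacement grows with compartment area", {
  mesh <- generate_fragmentation_meshwork(n_generations = 10, seed = 10)
  ens <- simulate_meshwork_confined_tracks(mesh, hop_probability = 0,
                                           n_steps = 100, n_traj = 300, seed = 11)
  rc <- attr(ens, "start_compartment")
  k <- round(0.2 / 0.02)
  r2 <- vapply(ens$trajectories, function(tr) {
    i <- seq_len(nrow(tr$positions) - k)
    mean(rowSums((tr$positions[i + k, ] - tr$positions[i, ])^2))
  }, numeric(1))
  ct <- cor.test(mesh$compartments$area_um2[rc], r2, method = "spearman",
                 alternative = "greater", exact = FALSE)
  expect_lt(ct$p.value, 1e-6)
})
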