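test_that("Euclidean distance map is exact (3-4-5 triangle, feature zeros)", {
  m <- matrix(0, 16, 16)
  m[5, 5] <- 1
  dm <- euclidean_distance_map(mesh_image(m, pixel_size = 10), threshold = 1)
  expect_equal(dm$values[5, 5], 0)
  expect_equal(dm$values[8, 9], 50)    # offset (3,4) -> 5 px * 10 nm
  expect_error(euclidean_distance_map(mesh_image(m, 10), threshold = 2),
               "empty-feature")
})

test_that("distance map equals brute-force nearest-feature search", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(runif(32 * 32) < 0.08, 32, 32)
    if (!any(m)) m[1, 1] <- TRUE
    dm <- euclidean_distance_map(mesh_image(m * 1, 1), threshold = 1)
    expect_equal(dm$values, brute_distance_map(m), tolerance = 1e-12)
    # Lipschitz: 4-neighbour differences bounded by one pixel
    expect_lte(max(abs(diff(dm$values))), 1 + 1e-9)
    expect_lte(max(abs(t(diff(t(dm$values))))), 1 + 1e-9)
  }
})

test_that("box counts equal a brute-force per-box scan and are monotone", {
  set.seed(13)
  m <- matrix(runif(64 * 64) < 0.1, 64, 64)
  sizes <- c(1, 2, 4, 8, 16)
  bc <- box_count_dimension(mesh_image(m * 1, 1), box_sizes = sizes,
                            fit_range = c(1, 16))
  expect_equal(bc$counts, brute_box_counts(m, sizes))
  expect_true(all(diff(bc$counts) <= 0))
})

test_that("box-counting recovers known fractal dimensions", {
  sq <- box_count_dimension(make_reference_fractals("filled_square", 256))
  expect_lt(abs(sq$fractal_dimension - 2), 0.05)
  ln <- box_count_dimension(make_reference_fractals("line", 256))
  expect_lt(abs(ln$fractal_dimension - 1), 0.05)
  carpet <- make_reference_fractals("sierpinski_carpet", 2187)
  cp <- box_count_dimension(carpet, box_sizes = 3^(0:6), fit_range = c(1, 729))
  expect_lt(abs(cp$fractal_dimension - log(8) / log(3)), 0.05)
  expect_error(box_count_dimension(mesh_image(matrix(0, 8, 8), 1)),
               "empty-feature")
})

test_that("grid-offset averaging makes the dimension translation-stable", {
  pc <- make_reference_fractals("percolation_cluster", 243, seed = 9)
  shift <- matrix(0, 243, 243)
  shift[4:243, 4:243] <- pc$pixels[1:240, 1:240]
  d1 <- box_count_dimension(pc, offsets = TRUE)$fractal_dimension
  d2 <- box_count_dimension(mesh_image(shift, pc$pixel_size),
                            offsets = TRUE)$fractal_dimension
  expect_lt(abs(d1 - d2), 0.02)
})

test_that("watershed recovers a regular 3x3 grid meshwork exactly", {
  mesh <- grid_mesh(3, 3)
  locs <- meshwork_to_localizations(mesh, linear_density = 2000,
                                    precision_mean = 15, precision_sd = 5,
                                    n_frames = 10, seed = 15)
  img <- render_localizations(locs, pixel_size = 10)
  seg <- watershed_compartments(img, min_area = 0.05)
  expect_equal(nrow(seg$compartments), 9L)
  expect_lt(max(abs(sort(seg$compartments$area_um2) -
                    sort(mesh$compartments$area_um2)) /
                sort(mesh$compartments$area_um2)), 0.05)
  # labels partition the image
  expect_equal(sum(tabulate(seg$labels)), length(seg$labels))
  expect_true(all(seg$labels >= 1))
  # each compartment is one 4-connected blob
  for (id in seg$compartments$label) {
    lab <- cortexmesh:::cpp_label4(seg$labels == id)
    expect_equal(max(lab), 1L)
  }
})

test_that("uniform images cannot be segmented", {
  expect_error(watershed_compartments(mesh_image(matrix(1, 32, 32), 10)),
               "no-compartments")
})

test_that("log-normal area fit recovers parameters at survey size", {
  set.seed(16)
  areas <- exp(rnorm(2500, 0, 1))
  fit <- fit_lognormal_areas(areas)
  expect_lt(abs(fit$mu_log - 0), 0.06)      # 3 sigma/sqrt(n)
  expect_lt(abs(fit$sigma_log - 1), 0.05)
  expect_equal(fit_lognormal_areas(rep(2, 10))$sigma_log, 0)
  expect_error(fit_lognormal_areas(c(1, 0, 2)), "invalid-data")
  expect_error(fit_lognormal_areas(c(1, 2)), "too-few")
})

test_that("perimeter-area scaling is exact for square and circle families", {
  sides <- seq(0.2, 3, length.out = 20)
  squares <- data.frame(area_um2 = sides^2, perimeter_um = 4 * sides)
  fs <- perimeter_area_scaling(squares)
  expect_equal(fs$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fs$prefactor, 4, tolerance = 1e-8)
  expect_equal(fs$pearson_log, 1, tolerance = 1e-12)
  r <- seq(0.1, 2, length.out = 20)
  circles <- data.frame(area_um2 = pi * r^2, perimeter_um = 2 * pi * r)
  fc <- perimeter_area_scaling(circles)
  expect_equal(fc$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fc$prefactor, 2 * sqrt(pi), tolerance = 1e-8)
  expect_error(perimeter_area_scaling(data.frame(area_um2 = c(1, 0, 2),
                                                 perimeter_um = c(1, 1, 1))),
               "invalid-data")
})

test_that("Crofton perimeter is accurate on a digitized disk", {
  r <- 40
  xy <- expand.grid(i = 1:100, j = 1:100)
  mask <- matrix((xy$i - 50.5)^2 + (xy$j - 50.5)^2 <= r^2, 100, 100)
  p <- cortexmesh:::crofton_perimeter_px(mask)
  expect_lt(abs(p - 2 * pi * r) / (2 * pi * r), 0.02)
})

test_that("branching relation inverts R_b = R_r^d_f", {
  expect_equal(round(branching_ratio(1.75, 2), 2), 1.49)
  expect_equal(branching_ratio(2, 4), 2)
  expect_error(branching_ratio(0, 2), "invalid-parameter")
  expect_error(branching_ratio(1.75, 1), "invalid-parameter")
})

test_that("distance-binned MSD flags single-segment bins", {
  tr <- trajectory("s", (0:10) * 0.02, cbind(seq(0, 0.5, length.out = 11), 0.25))
  ens <- trajectory_ensemble(list(tr))
  m <- matrix(0, 50, 50); m[1, ] <- 1    # actin along the bottom edge
  img <- mesh_image(m, pixel_size = 20)
  db <- msd_vs_actin_distance(ens, img, threshold = 1,
                              distance_bins = c(0, 500))
  expect_equal(sum(db$n_segments), 1L)
  expect_true(is.na(db$sem[db$n_segments == 1]))
  expect_equal(db$msd_um2[1], 0.25)
})
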