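test_that("rendering conserves localization counts exactly", {
  one <- localization_table(data.frame(frame = 0L, x_nm = 500, y_nm = 700,
                                       precision_nm = 20),
                            fov_nm = c(0, 1000, 0, 1000))
  img <- render_localizations(one, pixel_size = 20)
  expect_equal(sum(img$pixels), 1)

  set.seed(2)
  many <- localization_table(data.frame(frame = rep(0:9, 50),
                                        x_nm = runif(500, 0, 2000),
                                        y_nm = runif(500, 0, 2000),
                                        precision_nm = 20),
                             fov_nm = c(0, 2000, 0, 2000))
  i20 <- render_localizations(many, 20)
  i40 <- render_localizations(many, 40)
  expect_equal(sum(i20$pixels), 500)
  expect_equal(sum(i40$pixels), 500)
  expect_equal(length(i40$pixels) * 4, length(i20$pixels))
  blurred <- render_localizations(many, 20, blur_sd = 30)
  expect_lt(abs(sum(blurred$pixels) - 500) / 500, 1e-6)
})

test_that("frame windows subset localizations with conserved intensity", {
  set.seed(3)
  locs <- localization_table(data.frame(frame = sample(0:299, 3000, TRUE),
                                        x_nm = runif(3000, 0, 1000),
                                        y_nm = runif(3000, 0, 1000),
                                        precision_nm = 15),
                             fov_nm = c(0, 1000, 0, 1000))
  imgs <- sliding_reconstruction(locs, window_frames = 100, stride_frames = 10,
                                 pixel_size = 20, n_frames = 300)
  expect_length(imgs, 21L)
  for (k in c(1, 10, 21)) {
    first <- (k - 1) * 10
    n_in <- sum(locs$frame >= first & locs$frame <= first + 99)
    expect_equal(sum(imgs[[k]]$pixels), n_in)
    expect_equal(imgs[[k]]$time_interval, c(first, first + 100) * 0.02)
  }
  whole <- sliding_reconstruction(locs, 300, 10, 20, n_frames = 300)
  expect_length(whole, 1L)
  expect_equal(sum(whole[[1]]$pixels), 3000)
  expect_error(sliding_reconstruction(locs, 400, 10, 20, n_frames = 300),
               "too-few-frames")
})

test_that("reference fractal rasters are the exact named sets", {
  sq <- make_reference_fractals("filled_square", 64)
  expect_true(all(sq$pixels == 1))
  ln <- make_reference_fractals("line", 64)
  expect_equal(sum(ln$pixels), 64)
  carpet <- make_reference_fractals("sierpinski_carpet", 243)
  expect_equal(sum(carpet$pixels), 8^5)   # 3^5 px: occupied count is 8^5
  expect_error(make_reference_fractals("sierpinski_carpet", 100),
               "invalid-parameter")
  pc <- make_reference_fractals("percolation_cluster", 128, seed = 4)
  lab <- cortexmesh:::cpp_label4(pc$pixels > 0)
  expect_equal(max(lab), 1L)   # a single connected cluster
})

test_that("a zero-width filament renders with the localization-precision width", {
  mesh <- single_filament_mesh()
  locs <- meshwork_to_localizations(mesh, linear_density = 3000,
                                    precision_mean = 20, precision_sd = 0,
                                    n_frames = 10, seed = 7)
  img <- render_localizations(locs, pixel_size = 5)
  cuts <- cbind(2000 - 150, seq(800, 3200, length.out = 20),
                2000 + 150, seq(800, 3200, length.out = 20))
  prof <- cross_section_profile(img, cuts, half_width = 120)
  expect_lt(abs(prof$sd_nm - 20) / 20, 0.1)
})

test_that("mesh images round-trip through TIFF plus sidecar", {
  set.seed(5)
  img <- mesh_image(matrix(rpois(400, 3), 20, 20), pixel_size = 20,
                    origin = c(100, 200))
  img$time_interval <- c(0, 2)
  path <- tempfile(fileext = ".tif")
  write_mesh_image(img, path)
  back <- read_mesh_image(path)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-6)
  expect_equal(back$pixel_size, 20)
  expect_equal(back$origin, c(100, 200))
  expect_equal(back$time_interval, c(0, 2))
})
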