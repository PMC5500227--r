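# Shared fixtures and brute-force oracles used across the test files.

make_traj <- function(xy, dt = 1, id = "t1") {
  xy <- matrix(xy, ncol = 2, byrow = TRUE)
  trajectory(id, seq_len(nrow(xy)) * dt - dt, xy)
}

# O(N^2) double-loop estimator of the time-averaged MSD
naive_ta_msd <- function(pos, dt, kmax = nrow(pos) - 1) {
  vapply(seq_len(kmax), function(k) {
    acc <- 0
    for (i in seq_len(nrow(pos) - k))
      acc <- acc + sum((pos[i + k, ] - pos[i, ])^2)
    acc / (nrow(pos) - k)
  }, numeric(1))
}

# per-box scan over every box of the grid
brute_box_counts <- function(mask, box_sizes) {
  vapply(box_sizes, function(eps) {
    n <- 0
    for (i0 in seq(1, nrow(mask), by = eps))
      for (j0 in seq(1, ncol(mask), by = eps)) {
        sub <- mask[i0:min(i0 + eps - 1, nrow(mask)),
                    j0:min(j0 + eps - 1, ncol(mask)), drop = FALSE]
        if (any(sub)) n <- n + 1
      }
    n
  }, numeric(1))
}

# exact nearest-feature distance by exhaustive search
brute_distance_map <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
  out
}

# a meshwork_model holding a single straight vertical filament
single_filament_mesh <- function(region = c(4, 4), x = 2) {
  structure(list(
    region = region,
    fences = matrix(c(x, 0.5, x, region[2] - 0.5), 1,
                    dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
    compartments = data.frame(xmin = 0, xmax = region[1], ymin = 0,
                              ymax = region[2], depth = 0,
                              area_um2 = prod(region),
                              perimeter_um = 2 * sum(region)),
    generation_log = data.frame()), class = "meshwork_model")
}

# regular k x k grid meshwork over a square region
grid_mesh <- function(k = 3, side = 3) {
  cuts <- seq(0, side, length.out = k + 1)
  fences <- rbind(
    cbind(cuts, 0, cuts, side),     # vertical lines incl. boundary
    cbind(0, cuts, side, cuts))     # horizontal lines incl. boundary
  colnames(fences) <- c("x1", "y1", "x2", "y2")
  cells <- expand.grid(i = seq_len(k), j = seq_len(k))
  comp <- data.frame(xmin = cuts[cells$i], xmax = cuts[cells$i + 1],
                     ymin = cuts[cells$j], ymax = cuts[cells$j + 1],
                     depth = 0)
  comp$area_um2 <- (comp$xmax - comp$xmin) * (comp$ymax - comp$ymin)
  comp$perimeter_um <- 2 * ((comp$xmax - comp$xmin) + (comp$ymax - comp$ymin))
  structure(list(region = c(side, side), fences = fences,
                 compartments = comp, generation_log = data.frame()),
            class = "meshwork_model")
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# relative area error of each true compartment vs its majority-overlap label
compartment_match_errors <- function(mesh, seg) {
  lab <- seg$labels
  px <- seg$pixel_size
  areas_px <- tabulate(lab)
  comp <- mesh$compartments
  vapply(seq_len(nrow(comp)), function(r) {
    i1 <- max(1, floor(comp$ymin[r] * 1000 / px) + 1)
    i2 <- min(nrow(lab), ceiling(comp$ymax[r] * 1000 / px))
    j1 <- max(1, floor(comp$xmin[r] * 1000 / px) + 1)
    j2 <- min(ncol(lab), ceiling(comp$xmax[r] * 1000 / px))
    tt <- tabulate(lab[i1:i2, j1:j2])
    b <- which.max(tt)
    abs(areas_px[b] * (px / 1000)^2 - comp$area_um2[r]) / comp$area_um2[r]
  }, numeric(1))
}
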