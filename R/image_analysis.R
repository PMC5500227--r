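#' Euclidean distance map of an image's feature set
#'
#' Distance (nm) from every pixel centre to the centre of the nearest
#' feature pixel (intensity >= threshold); exactly 0 on feature pixels.
#'
#' @param image a `mesh_image`.
#' @param threshold intensity at or above which a pixel is a feature.
#' @return A `distance_map` with fields `values` (nm), `pixel_size`,
#'   `source_threshold`, `origin`.
#' @export
euclidean_distance_map <- function(image, threshold) {
  stopifnot(inherits(image, "mesh_image"))
  mask <- image$pixels >= threshold
  if (!any(mask)) stop("empty-feature: no pixel reaches the threshold", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask * 1),
                                           metric = "euclidean"))
  structure(list(values = d * image$pixel_size, pixel_size = image$pixel_size,
                 source_threshold = threshold, origin = image$origin),
            class = "distance_map")
}

# pixel lookup of a distance map / image at physical coordinates (nm)
pixel_index <- function(x_nm, y_nm, origin, pixel_size, dims) {
  iy <- pmin(pmax(floor((y_nm - origin[2]) / pixel_size) + 1, 1), dims[1])
  jx <- pmin(pmax(floor((x_nm - origin[1]) / pixel_size) + 1, 1), dims[2])
  cbind(iy, jx)
}

#' MSD over short segments conditioned on distance to the meshwork
#'
#' Trajectories are cut into consecutive non-overlapping segments of
#' `segment_duration`; each segment is paired with the reconstruction
#' window covering its midpoint (nearest window centre when several
#' qualify), classified by the maximum over the segment of the distance to
#' the nearest feature (actin) pixel, and its squared net displacement is
#' accumulated into the distance bin. Free walkers show a flat profile;
#' meshwork-confined walkers show displacement growing with distance from
#' actin.
#'
#' @param ensemble a [trajectory_ensemble()] (positions in um).
#' @param images list of `mesh_image`s with `time_interval` tags (from
#'   [sliding_reconstruction()]), or a single untagged image used for all
#'   segments.
#' @param threshold feature threshold passed to
#'   [euclidean_distance_map()].
#' @param segment_duration segment length in seconds (default 0.2).
#' @param distance_bins bin edges in nm (default 0-500 nm in 50-nm bins).
#' @return A `distance_binned_msd`: `bin_edges` (nm), `msd_um2`, `sem`,
#'   `n_segments` per bin, and skip counters. Bins with a single segment
#'   have `sem = NA`.
#' @export
msd_vs_actin_distance <- function(ensemble, images, threshold,
                                  segment_duration = 0.2,
                                  distance_bins = seq(0, 500, by = 50)) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (inherits(images, "mesh_image")) images <- list(images)
  dmaps <- lapply(images, euclidean_distance_map, threshold = threshold)
  centers <- vapply(images, function(im) {
    if (is.null(im$time_interval)) NA_real_ else mean(im$time_interval)
  }, numeric(1))
  intervals <- lapply(images, function(im) im$time_interval)
  dt <- ensemble$frame_interval
  m <- max(1L, round(segment_duration / dt))
  nbin <- length(distance_bins) - 1
  acc <- vector("list", nbin)
  n_no_window <- 0L; n_out_of_range <- 0L
  for (tr in ensemble$trajectories) {
    n <- nrow(tr$positions)
    starts <- seq(1L, n - m, by = m)
    if (n < m + 1) next
    for (s0 in starts) {
      mid_t <- (tr$times[s0] + tr$times[s0 + m]) / 2
      cand <- which(vapply(intervals, function(iv) {
        is.null(iv) || (mid_t >= iv[1] && mid_t <= iv[2])
      }, logical(1)))
      if (!length(cand)) { n_no_window <- n_no_window + 1L; next }
      w <- if (length(cand) == 1) cand else {
        cc <- centers[cand]
        cand[which.min(ifelse(is.na(cc), 0, abs(cc - mid_t)))]
      }
      dm <- dmaps[[w]]
      seg <- tr$positions[s0:(s0 + m), , drop = FALSE] * 1000  # um -> nm
      idx <- pixel_index(seg[, 1], seg[, 2], dm$origin, dm$pixel_size, dim(dm$values))
      d <- max(dm$values[idx])
      b <- findInterval(d, distance_bins, rightmost.closed = TRUE)
      if (b < 1 || b > nbin) { n_out_of_range <- n_out_of_range + 1L; next }
      dx <- tr$positions[s0 + m, 1] - tr$positions[s0, 1]
      dy <- tr$positions[s0 + m, 2] - tr$positions[s0, 2]
      acc[[b]] <- c(acc[[b]], dx^2 + dy^2)
    }
  }
  ns <- vapply(acc, length, integer(1))
  if (!any(ns > 0)) stop("empty-result: no segment could be classified", call. = FALSE)
  msd <- vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  sem <- vapply(acc, function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                numeric(1))
  structure(list(bin_edges = distance_bins, msd_um2 = msd, sem = sem,
                 n_segments = ns, segment_frames = m,
                 n_no_window = n_no_window, n_out_of_range = n_out_of_range),
            class = "distance_binned_msd")
}

#' @export
print.distance_binned_msd <- function(x, ...) {
  cat("<distance_binned_msd>", sum(x$n_segments), "segments of",
      x$segment_frames, "frames in", length(x$n_segments), "distance bins\n")
  invisible(x)
}

# bilinear interpolation of image intensity at physical points (nm)
bilinear_at <- function(image, x_nm, y_nm) {
  px <- image$pixel_size
  gx <- (x_nm - image$origin[1]) / px - 0.5  # 0-based pixel-centre coords
  gy <- (y_nm - image$origin[2]) / px - 0.5
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  j0 <- pmin(pmax(floor(gx), 0), nc - 2); i0 <- pmin(pmax(floor(gy), 0), nr - 2)
  fx <- pmin(pmax(gx - j0, 0), 1); fy <- pmin(pmax(gy - i0, 0), 1)
  p <- image$pixels
  v00 <- p[cbind(i0 + 1, j0 + 1)]; v01 <- p[cbind(i0 + 1, j0 + 2)]
  v10 <- p[cbind(i0 + 2, j0 + 1)]; v11 <- p[cbind(i0 + 2, j0 + 2)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

#' Average cross-section profile across linear features
#'
#' Samples intensity along perpendicular offsets from each cut line,
#' aligns the per-line profiles by their intensity centroid, averages
#' them, and fits a Gaussian; the fitted standard deviation measures the
#' apparent filament width, which for a zero-width structure is set by the
#' localization precision.
#'
#' @param image a `mesh_image`.
#' @param cut_lines n x 4 matrix of segment endpoints `x1,y1,x2,y2` in nm
#'   (each segment crossing a filament roughly perpendicularly).
#' @param half_width maximum perpendicular offset sampled, nm.
#' @return A `cross_section_profile`: `offsets_nm`, `intensity` (mean
#'   profile), `sd_nm` (Gaussian fit SD), `fit` (A, mu, sd, baseline) and
#'   the per-line profile matrix.
#' @export
cross_section_profile <- function(image, cut_lines, half_width = 150) {
  stopifnot(inherits(image, "mesh_image"))
  cut_lines <- matrix(as.numeric(cut_lines), ncol = 4)
  if (!nrow(cut_lines)) stop("invalid-geometry: no cut lines", call. = FALSE)
  px <- image$pixel_size
  lim_x <- image$origin[1] + c(0, ncol(image$pixels)) * px
  lim_y <- image$origin[2] + c(0, nrow(image$pixels)) * px
  offs <- seq(-half_width, half_width, by = px / 2)
  profs <- matrix(NA_real_, length(offs), nrow(cut_lines))
  for (li in seq_len(nrow(cut_lines))) {
    p1 <- cut_lines[li, 1:2]; p2 <- cut_lines[li, 3:4]
    if (any(c(p1[1], p2[1]) < lim_x[1]) || any(c(p1[1], p2[1]) > lim_x[2]) ||
        any(c(p1[2], p2[2]) < lim_y[1]) || any(c(p1[2], p2[2]) > lim_y[2]))
      stop("invalid-geometry: cut line outside the image", call. = FALSE)
    len <- sqrt(sum((p2 - p1)^2))
    u <- (p2 - p1) / len                 # along the cut
    # the cut is perpendicular to the filament: offsets run along the cut
    prof <- vapply(seq_along(offs), function(k) {
      # sample at fractional position along the cut, averaged across a
      # short stripe perpendicular to it for noise suppression
      t0 <- len / 2 + offs[k]
      if (t0 < 0 || t0 > len) return(NA_real_)
      nvec <- c(-u[2], u[1])
      stripe <- seq(-px, px, by = px / 2)
      xs <- p1[1] + t0 * u[1] + stripe * nvec[1]
      ys <- p1[2] + t0 * u[2] + stripe * nvec[2]
      inside <- xs >= lim_x[1] & xs <= lim_x[2] & ys >= lim_y[1] & ys <= lim_y[2]
      if (!any(inside)) return(NA_real_)
      mean(bilinear_at(image, xs[inside], ys[inside]))
    }, numeric(1))
    # centroid alignment
    w <- prof - min(prof, na.rm = TRUE)
    w[is.na(w)] <- 0
    cen <- if (sum(w) > 0) sum(w * offs) / sum(w) else 0
    ok <- !is.na(prof)
    profs[, li] <- approx(offs[ok] - cen, prof[ok], xout = offs, rule = 1)$y
  }
  avg <- rowMeans(profs, na.rm = TRUE)
  keep <- !is.na(avg)
  fit <- fit_gaussian_profile(offs[keep], avg[keep])
  structure(list(offsets_nm = offs[keep], intensity = avg[keep],
                 sd_nm = fit$sd, fit = fit, per_line = profs[keep, , drop = FALSE]),
            class = "cross_section_profile")
}

fit_gaussian_profile <- function(s, y) {
  b0 <- min(y); a0 <- max(y) - b0
  w <- pmax(y - b0, 0)
  mu0 <- sum(w * s) / sum(w)
  sd0 <- sqrt(sum(w * (s - mu0)^2) / sum(w))
  fit <- tryCatch({
    m <- nls(y ~ A * exp(-(s - mu)^2 / (2 * sigma^2)) + b,
             start = list(A = a0, mu = mu0, sigma = sd0, b = b0),
             control = list(maxiter = 200, warnOnly = TRUE))
    cf <- coef(m)
    list(A = unname(cf["A"]), mu = unname(cf["mu"]),
         sd = abs(unname(cf["sigma"])), baseline = unname(cf["b"]))
  }, error = function(e) list(A = a0, mu = mu0, sd = sd0, baseline = b0))
  fit
}

# Crofton 4-direction perimeter of a binary mask, in pixels.
crofton_perimeter_px <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  c0 <- sum(m[, -1] != m[, -ncol(m)])                  # horizontal lines
  c90 <- sum(m[-1, ] != m[-nrow(m), ])                 # vertical lines
  c45 <- sum(m[-1, -1] != m[-nrow(m), -ncol(m)])       # (1,1) diagonals
  c135 <- sum(m[-1, -ncol(m)] != m[-nrow(m), -1])      # (1,-1) diagonals
  (pi / 2) * (c0 + c90 + (c45 + c135) / sqrt(2)) / 4
}

#' Watershed segmentation of meshwork compartments
#'
#' Compartments are catchment basins between actin ridges, seeded at
#' regional minima of the actin channel. With the default `"distance"`
#' landscape the smoothed image is binarized (threshold), the Euclidean
#' distance to the nearest actin pixel is computed, and the watershed is
#' flooded on that distance map, so basin depth is measured in pixels and
#' the merging `tolerance` is scale-free; `"intensity"` floods the
#' inverted smoothed image directly. Actin-ridge pixels are then divided
#' between the adjacent basins by symmetric layer-wise growth, so every
#' pixel carries exactly one compartment label and compartment areas are
#' unbiased (the fences proper are the zero-width watershed lines between
#' labels; `actin_mask` records which pixels are actin). Compartments
#' below `min_area` are merged into the neighbour sharing the longest
#' boundary. Perimeters use a 4-direction Crofton estimate;
#' `actin_coverage` is the fraction of pixels at or above the threshold
#' and `meshwork_actin_fraction` the fraction of inter-compartment
#' boundary pixels that are themselves actin.
#'
#' @param image a `mesh_image`.
#' @param smoothing_sd Gaussian smoothing in nm (default: 1 pixel).
#' @param actin_threshold "otsu" (default) or a numeric intensity on the
#'   normalized smoothed image.
#' @param min_area minimum compartment area in um^2 (default: 3 pixels).
#' @param tolerance watershed merging tolerance: basins whose dynamic is
#'   below it are absorbed. In pixels of distance for the "distance"
#'   landscape (default 1.5); as a fraction of the intensity range for
#'   "intensity" (default 0.1).
#' @param landscape "distance" (default) or "intensity".
#' @return A `segmentation_result`: `labels` (matrix, compartment id per
#'   pixel), `compartments` (data frame `label,area_um2,perimeter_um`),
#'   `actin_coverage`, `meshwork_actin_fraction`, `actin_mask`,
#'   `pixel_size`, `threshold`.
#' @export
watershed_compartments <- function(image, smoothing_sd = NULL,
                                   actin_threshold = "otsu", min_area = NULL,
                                   tolerance = NULL,
                                   landscape = c("distance", "intensity")) {
  stopifnot(inherits(image, "mesh_image"))
  landscape <- match.arg(landscape)
  px <- image$pixel_size
  smoothing_sd <- smoothing_sd %||% px
  min_area <- min_area %||% (3 * (px / 1000)^2)
  s <- gaussian_blur(image$pixels, smoothing_sd / px)
  rng <- range(s)
  if (diff(rng) <= 0) stop("no-compartments: image is uniform", call. = FALSE)
  sn <- (s - rng[1]) / diff(rng)
  thr <- if (identical(actin_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sn), range = c(0, 1))
  } else as.numeric(actin_threshold)
  mask <- sn >= thr
  surface <- if (landscape == "distance") {
    if (!any(mask)) stop("no-compartments: threshold removes all actin", call. = FALSE)
    if (all(mask)) stop("no-compartments: threshold keeps every pixel", call. = FALSE)
    EBImage::imageData(EBImage::distmap(EBImage::Image(1 - mask * 1)))
  } else {
    1 - sn
  }
  tolerance <- tolerance %||% (if (landscape == "distance") 1.5 else 0.1)
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(surface),
                                               tolerance = tolerance, ext = 1))
  storage.mode(lab) <- "integer"
  lab <- assign_unlabelled(lab)   # ridge/actin pixels -> nearest basin
  lab <- merge_small_compartments(lab, min_area / (px / 1000)^2)
  ids <- sort(unique(as.vector(lab)))
  areas <- tabulate(lab, max(ids))[ids]
  lv <- as.vector(lab)
  ri <- rep.int(seq_len(nrow(lab)), ncol(lab))
  ci <- rep(seq_len(ncol(lab)), each = nrow(lab))
  r1 <- tapply(ri, lv, min); r2 <- tapply(ri, lv, max)
  c1 <- tapply(ci, lv, min); c2 <- tapply(ci, lv, max)
  perim <- vapply(seq_along(ids), function(k) {
    crofton_perimeter_px(lab[r1[k]:r2[k], c1[k]:c2[k], drop = FALSE] == ids[k])
  }, numeric(1))
  boundary <- ridge_pixels(lab)
  structure(list(labels = lab,
                 compartments = data.frame(label = ids,
                                           area_um2 = areas * (px / 1000)^2,
                                           perimeter_um = perim * px / 1000),
                 actin_coverage = mean(mask),
                 meshwork_actin_fraction = if (any(boundary)) mean(mask[boundary]) else NA_real_,
                 actin_mask = mask, pixel_size = px, threshold = thr),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", nrow(x$compartments), "compartments,",
      sprintf("actin coverage %.1f%%,", 100 * x$actin_coverage),
      sprintf("meshwork-on-actin %.1f%%\n", 100 * x$meshwork_actin_fraction))
  invisible(x)
}

# Assign unlabelled (0) pixels to the nearest basin by layer-wise growth.
# The 4 growth directions take priority in rotating order so shared walls
# are divided symmetrically between their two basins.
assign_unlabelled <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  it <- 0L
  while (any(lab == 0L) && it < nr + nc) {
    it <- it + 1L
    newlab <- lab
    ord <- ((it - 1L + 0:3) %% 4L) + 1L
    for (d in rev(ord)) {       # last write wins => first of ord has priority
      dd <- dirs[[d]]
      sh <- matrix(0L, nr, nc)
      ri <- max(1, 1 + dd[1]):min(nr, nr + dd[1])
      ci <- max(1, 1 + dd[2]):min(nc, nc + dd[2])
      sh[ri, ci] <- lab[ri - dd[1], ci - dd[2]]
      fill <- lab == 0L & sh > 0L
      newlab[fill] <- sh[fill]
    }
    lab <- newlab
  }
  lab
}

# pixels adjacent (4-connectivity) to a different label
ridge_pixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  d <- lab[-nr, ] != lab[-1, ]
  b[-nr, ][d] <- TRUE; b[-1, ][d] <- TRUE
  d <- lab[, -nc] != lab[, -1]
  b[, -nc][d] <- TRUE; b[, -1][d] <- TRUE
  b
}

# Merge labels smaller than min_px into the neighbour with the longest
# shared boundary, using the 4-adjacency edge list of the label image.
merge_small_compartments <- function(lab, min_px) {
  for (pass in 1:50) {
    areas <- tabulate(lab)
    small <- which(areas > 0 & areas < min_px)
    if (!length(small)) break
    h <- cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
    v <- cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ]))
    e <- rbind(h, v)
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    if (!nrow(e)) break
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    cnt <- table(paste(a, b))
    ab <- matrix(as.integer(do.call(rbind, strsplit(names(cnt), " "))), ncol = 2)
    map <- seq_len(max(lab))
    for (sid in small) {
      rows <- which(ab[, 1] == sid | ab[, 2] == sid)
      if (!length(rows)) next
      r0 <- rows[which.max(cnt[rows])]
      map[sid] <- if (ab[r0, 1] == sid) ab[r0, 2] else ab[r0, 1]
    }
    if (all(map == seq_along(map))) break
    for (k in 1:20) map <- map[map]   # resolve merge chains
    lab <- matrix(map[lab], nrow(lab), ncol(lab))
  }
  ids <- sort(unique(as.vector(lab)))
  matrix(match(lab, ids), nrow(lab), ncol(lab))
}

#' Fit a log-normal law to compartment areas
#'
#' Maximum-likelihood normal fit on log-areas with a KS goodness-of-fit
#' p-value against the fitted normal.
#'
#' @param areas numeric vector of areas (um^2), all > 0, length >= 3.
#' @return List with `mu_log`, `sigma_log`, `gof_p`, `n`.
#' @export
fit_lognormal_areas <- function(areas) {
  if (length(areas) < 3) stop("too-few: need at least 3 areas", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("invalid-data: areas must be positive", call. = FALSE)
  la <- log(areas)
  mu <- mean(la)
  sigma <- sqrt(mean((la - mu)^2))
  p <- if (sigma == 0) 1 else
    suppressWarnings(ks.test(la, "pnorm", mu, sigma)$p.value)
  list(mu_log = mu, sigma_log = sigma, gof_p = p, n = length(areas))
}

#' Perimeter-area scaling of compartments
#'
#' Least-squares fit of log(perimeter) on log(area): `L = a * A^b`. For
#' compact Euclidean shapes b = 0.5 (squares: a = 4; circles:
#' a = 2 sqrt(pi)); a single exponent across the whole area range with
#' high log-log correlation indicates shape homogeneity and scale
#' invariance.
#'
#' @param compartments a `segmentation_result` or a data frame with
#'   columns `area_um2` and `perimeter_um`.
#' @return List with `prefactor`, `exponent`, `pearson_log`, `n`.
#' @export
perimeter_area_scaling <- function(compartments) {
  df <- if (inherits(compartments, "segmentation_result"))
    compartments$compartments else as.data.frame(compartments)
  if (nrow(df) < 3) stop("too-few: need at least 3 compartments", call. = FALSE)
  if (any(df$area_um2 <= 0) || any(df$perimeter_um <= 0))
    stop("invalid-data: degenerate area or perimeter", call. = FALSE)
  la <- log(df$area_um2); ll <- log(df$perimeter_um)
  fit <- lm(ll ~ la)
  list(prefactor = exp(unname(coef(fit)[1])),
       exponent = unname(coef(fit)[2]),
       pearson_log = cor(la, ll), n = nrow(df))
}

#' Box-counting fractal dimension of a binary image
#'
#' Counts the number N of eps x eps boxes (grid anchored at the image
#' origin) containing at least one occupied pixel; N ~ eps^(-d_f) and the
#' capacity dimension d_f is minus the slope of log N against log eps over
#' the fit range. Optional averaging over 4 half-box grid offsets reduces
#' anchoring bias.
#'
#' @param image a `mesh_image` (pixels > 0 are occupied) or a logical/
#'   numeric matrix.
#' @param box_sizes box edges in pixels (default: powers of 2 up to a
#'   quarter of the short side).
#' @param fit_range `c(min, max)` box sizes used in the fit (default: 2 px
#'   to a quarter of the short side).
#' @param offsets average counts over 4 sub-box grid offsets.
#' @return A `box_count_result`: `box_sizes`, `counts`,
#'   `fractal_dimension`, `fit_range`.
#' @export
box_count_dimension <- function(image, box_sizes = NULL, fit_range = NULL,
                                offsets = FALSE) {
  pixels <- if (inherits(image, "mesh_image")) image$pixels else as.matrix(image)
  occ <- which(pixels > 0, arr.ind = TRUE)
  if (!nrow(occ)) stop("empty-feature: image has no occupied pixels", call. = FALSE)
  short <- min(dim(pixels))
  box_sizes <- box_sizes %||% 2^(0:floor(log2(short / 4)))
  fit_range <- fit_range %||% c(2, short / 4)
  counts <- vapply(box_sizes, function(eps) {
    offs <- if (offsets && eps > 1) {
      h <- eps %/% 2
      rbind(c(0, 0), c(h, 0), c(0, h), c(h, h))
    } else rbind(c(0, 0))
    mean(apply(offs, 1, function(o) {
      bi <- (occ[, 1] - 1 + o[1]) %/% eps
      bj <- (occ[, 2] - 1 + o[2]) %/% eps
      length(unique(bi * (max(bj) + 1) + bj))
    }))
  }, numeric(1))
  sel <- which(box_sizes >= fit_range[1] & box_sizes <= fit_range[2])
  if (length(sel) < 3)
    stop("invalid-parameter: need >= 3 box sizes inside fit_range", call. = FALSE)
  lx <- log(box_sizes[sel]); ly <- log(counts[sel])
  fit <- lm(ly ~ lx)
  structure(list(box_sizes = box_sizes, counts = counts,
                 fractal_dimension = -unname(coef(fit)[2]),
                 fit_range = fit_range,
                 r_squared = if (sd(ly) == 0) 1 else cor(lx, ly)^2),
            class = "box_count_result")
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count_result> d_f = %.4f over box sizes [%g, %g] px\n",
              x$fractal_dimension, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Length-order ratio of a hierarchically branched fractal
#'
#' For a branched structure with bifurcation ratio R_b (branches emerging
#' per bifurcation) and fractal dimension d_f, the length-order ratio
#' satisfies R_b = R_r^d_f, i.e. R_r = R_b^(1/d_f).
#'
#' @param fractal_dimension d_f > 0.
#' @param bifurcation_ratio R_b > 1.
#' @return R_r, the ratio of mother to daughter branch length.
#' @export
branching_ratio <- function(fractal_dimension, bifurcation_ratio) {
  if (!is.finite(fractal_dimension) || fractal_dimension <= 0)
    stop("invalid-parameter: fractal_dimension must be > 0", call. = FALSE)
  if (!is.finite(bifurcation_ratio) || bifurcation_ratio <= 1)
    stop("invalid-parameter: bifurcation_ratio must be > 1", call. = FALSE)
  bifurcation_ratio^(1 / fractal_dimension)
}
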