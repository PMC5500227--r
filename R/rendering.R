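#' Pixel image with physical scale
#'
#' `pixels` is a matrix in (row = y, col = x) order: row i covers the y
#' interval `[(i-1), i] * pixel_size` above `origin[2]`, with the physical
#' origin at the lower-left corner of the field of view and pixel centres at
#' `(i - 0.5) * pixel_size`.
#'
#' @param pixels nonnegative numeric matrix.
#' @param pixel_size pixel edge in nm (> 0).
#' @param origin physical position (nm) of the lower-left corner,
#'   `c(x0, y0)`.
#' @param time_interval optional `c(t_start, t_end)` seconds tag (set by
#'   [sliding_reconstruction()]).
#' @return A `mesh_image`.
#' @export
mesh_image <- function(pixels, pixel_size, origin = c(0, 0), time_interval = NULL) {
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("invalid-parameter: pixel_size must be > 0", call. = FALSE)
  structure(list(pixels = as.matrix(pixels), pixel_size = pixel_size,
                 origin = origin, time_interval = time_interval),
            class = "mesh_image")
}

#' @export
print.mesh_image <- function(x, ...) {
  cat("<mesh_image>", nrow(x$pixels), "x", ncol(x$pixels), "px @",
      x$pixel_size, "nm/px, total intensity", signif(sum(x$pixels), 6))
  if (!is.null(x$time_interval))
    cat(", t = [", signif(x$time_interval[1], 4), ",",
        signif(x$time_interval[2], 4), "] s")
  cat("\n")
  invisible(x)
}

# Separable Gaussian blur with a normalized kernel and circular boundary;
# conserves total intensity to machine precision.
gaussian_blur <- function(pixels, sd_px) {
  if (sd_px <= 0) return(pixels)
  r <- max(1L, ceiling(4 * sd_px))
  g <- exp(-((-r):r)^2 / (2 * sd_px^2))
  g <- g / sum(g)
  k <- outer(g, g)
  as.matrix(EBImage::filter2(pixels, k, boundary = "circular"))
}

#' Render localizations into a 2D histogram image
#'
#' Bins in-window localizations on a grid of `pixel_size` over the table's
#' field of view; total intensity equals the in-window localization count
#' (conservation holds after optional Gaussian blur too, because the blur
#' kernel is normalized).
#'
#' @param locs a `localization_table`.
#' @param pixel_size nm per pixel.
#' @param blur_sd optional Gaussian rendering blur in nm (0 = none).
#' @param frame_window optional `c(first, last)` inclusive 0-based frame
#'   range.
#' @return A `mesh_image`; if the window contains no localizations the
#'   image is empty and carries attribute `empty = TRUE`.
#' @export
render_localizations <- function(locs, pixel_size = 20, blur_sd = 0,
                                 frame_window = NULL) {
  stopifnot(inherits(locs, "localization_table"))
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("invalid-parameter: pixel_size must be > 0", call. = FALSE)
  fov <- attr(locs, "fov_nm")
  df <- as.data.frame(locs)
  if (!is.null(frame_window))
    df <- df[df$frame >= frame_window[1] & df$frame <= frame_window[2], , drop = FALSE]
  nx <- max(1L, ceiling((fov[2] - fov[1]) / pixel_size - 1e-9))
  ny <- max(1L, ceiling((fov[4] - fov[3]) / pixel_size - 1e-9))
  img <- matrix(0, ny, nx)
  if (nrow(df)) {
    jx <- pmin(pmax(floor((df$x_nm - fov[1]) / pixel_size) + 1L, 1L), nx)
    iy <- pmin(pmax(floor((df$y_nm - fov[3]) / pixel_size) + 1L, 1L), ny)
    tab <- table(factor(iy, levels = 1:ny), factor(jx, levels = 1:nx))
    img <- matrix(as.numeric(tab), ny, nx)
  }
  if (blur_sd > 0) img <- gaussian_blur(img, blur_sd / pixel_size)
  out <- mesh_image(img, pixel_size, origin = c(fov[1], fov[3]))
  if (!nrow(df)) attr(out, "empty") <- TRUE
  out
}

#' Sliding-window image reconstruction
#'
#' Live-cell localization microscopy reconstruction: one image per window
#' of `window_frames` frames, advanced by `stride_frames` (e.g. 100-frame
#' windows every 10 frames = 2-s images sliding by 0.2 s at 50 frames/s).
#' Each image is tagged with its time interval.
#'
#' @param locs a `localization_table`.
#' @param window_frames frames per window (>= 1).
#' @param stride_frames stride between window starts (>= 1).
#' @param pixel_size nm per pixel.
#' @param blur_sd rendering blur in nm.
#' @param n_frames total recording length in frames; defaults to
#'   `max(frame) + 1`.
#' @return List of `mesh_image`s, one per full window.
#' @export
sliding_reconstruction <- function(locs, window_frames = 100, stride_frames = 10,
                                   pixel_size = 20, blur_sd = 0, n_frames = NULL) {
  stopifnot(inherits(locs, "localization_table"))
  if (window_frames < 1 || stride_frames < 1)
    stop("invalid-parameter: window and stride must be >= 1", call. = FALSE)
  n_frames <- n_frames %||% (max(locs$frame) + 1L)
  if (window_frames > n_frames)
    stop("too-few-frames: window longer than the recording", call. = FALSE)
  dt <- attr(locs, "frame_interval") %||% 0.02
  n_windows <- (n_frames - window_frames) %/% stride_frames + 1L
  lapply(seq_len(n_windows) - 1L, function(k) {
    first <- k * stride_frames
    img <- render_localizations(locs, pixel_size, blur_sd,
                                frame_window = c(first, first + window_frames - 1L))
    img$time_interval <- c(first, first + window_frames) * dt
    img
  })
}

#' Reference binary rasters of known fractal dimension
#'
#' Oracles for box-counting: a filled square (dimension 2), a straight line
#' (1), the Sierpinski carpet (log 8 / log 3 = 1.8928), and the largest
#' cluster of critical site percolation (1.896 asymptotically).
#'
#' @param kind one of "filled_square", "line", "sierpinski_carpet",
#'   "percolation_cluster".
#' @param size image side in pixels; must be a power of 3 for the carpet.
#' @param seed seed (percolation cluster only).
#' @param pixel_size nm per pixel for the returned image.
#' @return A binary `mesh_image`.
#' @export
make_reference_fractals <- function(kind = c("filled_square", "line",
                                             "sierpinski_carpet",
                                             "percolation_cluster"),
                                    size = 243, seed = 1, pixel_size = 20) {
  kind <- match.arg(kind)
  img <- switch(kind,
    filled_square = matrix(1, size, size),
    line = {
      m <- matrix(0, size, size)
      m[ceiling(size / 2), ] <- 1
      m
    },
    sierpinski_carpet = {
      k <- round(log(size) / log(3))
      if (abs(3^k - size) > 1e-9)
        stop("invalid-parameter: carpet size must be a power of 3", call. = FALSE)
      cell <- matrix(1, 3, 3); cell[2, 2] <- 0
      m <- matrix(1, 1, 1)
      for (i in seq_len(k)) m <- kronecker(m, cell)
      m
    },
    percolation_cluster = {
      set.seed(as.integer(seed))
      p_c <- 0.592746
      m <- matrix(runif(size * size) < p_c, size, size)
      lab <- cpp_label4(m)
      if (max(lab) == 0) stop("empty-feature: no occupied sites", call. = FALSE)
      sizes <- tabulate(lab[lab > 0])
      (lab == which.max(sizes)) * 1
    })
  mesh_image(img * 1, pixel_size)
}

#' Write / read a mesh image as TIFF with a JSON sidecar
#'
#' The pixel grid is stored as a single-channel 32-bit float TIFF; the
#' physical metadata (pixel size, origin, time interval) travels in a JSON
#' sidecar named `<path>.json`.
#'
#' @param image a `mesh_image`.
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_mesh_image <- function(image, path) {
  stopifnot(inherits(image, "mesh_image"))
  m <- image$pixels
  scale <- max(m)
  tiff::writeTIFF(if (scale > 0) m / scale else m, path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = image$pixel_size,
                            origin_nm = image$origin,
                            intensity_scale = scale,
                            time_interval_s = image$time_interval),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @param path TIFF path written by [write_mesh_image()].
#' @rdname write_mesh_image
#' @export
read_mesh_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (!is.null(dim(m)) && length(dim(m)) == 3) m <- m[, , 1]
  out <- mesh_image(m * meta$intensity_scale, meta$pixel_size_nm,
                    origin = meta$origin_nm)
  if (!is.null(meta$time_interval_s) && length(meta$time_interval_s))
    out$time_interval <- meta$time_interval_s
  out
}
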