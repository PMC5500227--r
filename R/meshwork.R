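#' Generate an actin-like meshwork by repeated fragmentation
#'
#' Compartments are produced by recursive random breakage of a rectangular
#' region with axis-aligned chords whose relative position is drawn from a
#' bounded law independent of compartment size. When fragment proportions
#' are independent of size, repeated breakage drives the fragment-size
#' distribution to a log-normal (Kolmogorov's breakage model) - the law
#' observed for actin-delimited compartment areas.
#'
#' Two splitting schemes are provided. `"generation"` (default) is the
#' literal breakage model: every compartment at or above `min_area` is
#' split once per generation, so all lineages accumulate splits at the same
#' rate and log-areas converge to a normal by the central limit theorem.
#' `"sequential"` performs one split per generation on a single compartment
#' chosen by `selection` ("area": probability proportional to area, the
#' sequential embedding of the synchronous model; "uniform": equal
#' probability - note that uniform selection produces strongly right-skewed
#' log-areas and is kept only for comparison).
#'
#' @param region numeric length-2, width and height of the region in
#'   micrometres.
#' @param n_generations number of breakage generations (or of single splits
#'   for the sequential scheme); >= 0.
#' @param split_fraction_law either a numeric length-2 vector `c(lo, hi)`
#'   (uniform law on \[lo, hi\], 0 < lo <= hi < 1) or a function `f(n)`
#'   returning n fractions in (0, 1).
#' @param min_area compartments below this area (um^2) are not split
#'   further.
#' @param seed integer seed.
#' @param scheme "generation" or "sequential" (see above).
#' @param selection leaf selection rule for the sequential scheme.
#' @param orientation "longest" (default: the chord cuts across the longest
#'   side, keeping compartments compact), "alternate" (orientation
#'   alternates with depth; aspect ratios drift as a random walk) or
#'   "random".
#' @param include_boundary include the four region edges in the fence list
#'   (default TRUE).
#' @return A `meshwork_model`: `region`, `fences` (segment matrix
#'   x1,y1,x2,y2 in um), `compartments` (data frame with bounds, `area_um2`,
#'   `perimeter_um`, `depth`), and a per-split `generation_log`.
#' @export
generate_fragmentation_meshwork <- function(region = c(20, 20), n_generations = 11,
                                            split_fraction_law = c(0.25, 0.75),
                                            min_area = 0.01, seed = 1,
                                            scheme = c("generation", "sequential"),
                                            selection = c("area", "uniform"),
                                            orientation = c("longest", "alternate", "random"),
                                            include_boundary = TRUE) {
  scheme <- match.arg(scheme)
  selection <- match.arg(selection)
  orientation <- match.arg(orientation)
  if (n_generations < 0) stop("invalid-parameter: n_generations must be >= 0", call. = FALSE)
  if (!is.finite(min_area) || min_area <= 0)
    stop("invalid-parameter: min_area must be > 0", call. = FALSE)
  draw_fraction <- law_sampler(split_fraction_law)
  set.seed(as.integer(seed))

  # rects: xmin xmax ymin ymax depth
  rects <- matrix(c(0, region[1], 0, region[2], 0), 1)
  fences <- matrix(numeric(0), 0, 4)
  log_rows <- list()

  split_one <- function(r) {
    f <- draw_fraction(1)
    vert <- switch(orientation,
      longest = (r[2] - r[1]) >= (r[4] - r[3]),
      alternate = (r[5] %% 2) == 0,
      random = runif(1) < 0.5)
    if (vert) {
      cut <- r[1] + f * (r[2] - r[1])
      seg <- c(cut, r[3], cut, r[4])
      kids <- rbind(c(r[1], cut, r[3], r[4], r[5] + 1),
                    c(cut, r[2], r[3], r[4], r[5] + 1))
    } else {
      cut <- r[3] + f * (r[4] - r[3])
      seg <- c(r[1], cut, r[2], cut)
      kids <- rbind(c(r[1], r[2], r[3], cut, r[5] + 1),
                    c(r[1], r[2], cut, r[4], r[5] + 1))
    }
    list(kids = kids, seg = seg, f = f, vert = vert)
  }

  if (scheme == "generation") {
    for (g in seq_len(n_generations)) {
      if (n_generations == 0) break
      areas <- (rects[, 2] - rects[, 1]) * (rects[, 4] - rects[, 3])
      out <- vector("list", nrow(rects))
      for (i in seq_len(nrow(rects))) {
        if (areas[i] < min_area) { out[[i]] <- rects[i, , drop = FALSE]; next }
        sp <- split_one(rects[i, ])
        out[[i]] <- sp$kids
        fences <- rbind(fences, sp$seg)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(generation = g, fraction = sp$f,
                     vertical = sp$vert, parent_area = areas[i])
      }
      rects <- do.call(rbind, out)
    }
  } else {
    for (g in seq_len(n_generations)) {
      if (n_generations == 0) break
      areas <- (rects[, 2] - rects[, 1]) * (rects[, 4] - rects[, 3])
      elig <- which(areas >= min_area)
      if (!length(elig)) break
      i <- if (length(elig) == 1) elig
           else if (selection == "area") sample(elig, 1, prob = areas[elig])
           else elig[sample.int(length(elig), 1)]
      sp <- split_one(rects[i, ])
      fences <- rbind(fences, sp$seg)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(generation = g, fraction = sp$f,
                   vertical = sp$vert, parent_area = areas[i])
      rects <- rbind(rects[-i, , drop = FALSE], sp$kids)
    }
  }

  if (include_boundary) {
    w <- region[1]; h <- region[2]
    fences <- rbind(fences,
                    c(0, 0, w, 0), c(0, h, w, h), c(0, 0, 0, h), c(w, 0, w, h))
  }
  comp <- data.frame(xmin = rects[, 1], xmax = rects[, 2],
                     ymin = rects[, 3], ymax = rects[, 4],
                     depth = as.integer(rects[, 5]))
  comp$area_um2 <- (comp$xmax - comp$xmin) * (comp$ymax - comp$ymin)
  comp$perimeter_um <- 2 * ((comp$xmax - comp$xmin) + (comp$ymax - comp$ymin))
  colnames(fences) <- c("x1", "y1", "x2", "y2")
  structure(list(region = region, fences = fences, compartments = comp,
                 generation_log = if (length(log_rows)) do.call(rbind, log_rows)
                                  else data.frame()),
            class = "meshwork_model")
}

law_sampler <- function(law) {
  if (is.function(law)) return(law)
  if (is.numeric(law) && length(law) == 2 &&
      law[1] > 0 && law[2] < 1 && law[1] <= law[2])
    return(function(n) runif(n, law[1], law[2]))
  stop("invalid-parameter: split_fraction_law must be c(lo, hi) with 0 < lo <= hi < 1 or a function",
       call. = FALSE)
}

#' @export
print.meshwork_model <- function(x, ...) {
  cat("<meshwork_model>", nrow(x$compartments), "compartments in",
      x$region[1], "x", x$region[2], "um,", nrow(x$fences), "fence segments\n")
  invisible(x)
}

#' Sample single-molecule localizations along meshwork fences
#'
#' Emulates localization microscopy of a labelled meshwork: points are
#' placed along every fence segment as a Poisson process of the given
#' linear density, each is displaced isotropically by a Gaussian of
#' per-point standard deviation drawn as |Normal(precision_mean,
#' precision_sd)| (the localization precision), and frames are assigned
#' uniformly. Photophysics (blinking kinetics) is not modelled.
#'
#' @param mesh a `meshwork_model`.
#' @param linear_density localizations per micrometre of fence.
#' @param precision_mean,precision_sd localization precision in nm
#'   (defaults 20 and 8 nm).
#' @param n_frames number of camera frames the localizations are spread
#'   over.
#' @param seed integer seed.
#' @return A `localization_table`: data frame with `frame` (0-based),
#'   `x_nm`, `y_nm`, `precision_nm`; the field of view (nm) and the frame
#'   interval (0.02 s) are attached as attributes.
#' @export
meshwork_to_localizations <- function(mesh, linear_density = 500,
                                      precision_mean = 20, precision_sd = 8,
                                      n_frames = 100, seed = 1) {
  stopifnot(inherits(mesh, "meshwork_model"))
  if (!nrow(mesh$fences)) stop("empty-mesh: meshwork has no fences", call. = FALSE)
  if (!is.finite(linear_density) || linear_density <= 0)
    stop("invalid-parameter: linear_density must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  seg <- mesh$fences
  len <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
  counts <- rpois(nrow(seg), linear_density * len)
  total <- sum(counts)
  if (total == 0)
    return(localization_table(data.frame(frame = integer(0), x_nm = numeric(0),
                                         y_nm = numeric(0), precision_nm = numeric(0)),
                              fov_nm = c(0, mesh$region[1], 0, mesh$region[2]) * 1000))
  si <- rep.int(seq_len(nrow(seg)), counts)
  u <- runif(total)
  x <- (seg[si, 1] + u * (seg[si, 3] - seg[si, 1])) * 1000
  y <- (seg[si, 2] + u * (seg[si, 4] - seg[si, 2])) * 1000
  prec <- abs(rnorm(total, precision_mean, precision_sd))
  x <- x + rnorm(total, 0, prec)
  y <- y + rnorm(total, 0, prec)
  fov <- c(0, mesh$region[1], 0, mesh$region[2]) * 1000
  x <- pmin(pmax(x, fov[1]), fov[2])
  y <- pmin(pmax(y, fov[3]), fov[4])
  frame <- sample.int(n_frames, total, replace = TRUE) - 1L
  df <- data.frame(frame = frame, x_nm = x, y_nm = y, precision_nm = prec)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  localization_table(df, fov_nm = fov)
}

#' Localization table constructor
#'
#' @param df data frame with columns `frame`, `x_nm`, `y_nm`,
#'   `precision_nm`.
#' @param fov_nm field of view `c(xmin, xmax, ymin, ymax)` in nm; defaults
#'   to the bounding box of the points.
#' @param frame_interval seconds per frame (default 0.02).
#' @return A `localization_table` (a data frame subclass).
#' @export
localization_table <- function(df, fov_nm = NULL, frame_interval = 0.02) {
  required <- c("frame", "x_nm", "y_nm", "precision_nm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema-error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df$precision_nm <= 0)) stop("invalid-data: precision must be > 0", call. = FALSE)
  if (is.null(fov_nm)) {
    fov_nm <- if (nrow(df)) c(min(df$x_nm), max(df$x_nm), min(df$y_nm), max(df$y_nm))
              else c(0, 1, 0, 1)
  }
  structure(df, fov_nm = fov_nm, frame_interval = frame_interval,
            class = c("localization_table", "data.frame"))
}

#' Read / write localization tables
#'
#' CSV schema: `frame,x_nm,y_nm,precision_nm` (0-based frames).
#'
#' @param path CSV path.
#' @return [read_localizations()] returns a `localization_table`.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  localization_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @param locs a `localization_table`.
#' @rdname read_localizations
#' @export
write_localizations <- function(locs, path) {
  write.csv(as.data.frame(locs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate trajectories confined by a meshwork
#'
#' Gaussian steps of per-axis variance `2 D dt`; every meshwork fence
#' crossed by a step is a permeable barrier with the same
#' acceptance/reflection micro-rule as [simulate_fenced_diffusion()]. The
#' region boundary always reflects. Starting compartments are drawn with
#' probability proportional to area and starting points uniformly within,
#' so the zero-hop walk is stationary within each compartment.
#'
#' @param mesh a `meshwork_model`.
#' @param diffusivity um^2/s.
#' @param hop_probability per-crossing acceptance probability in \[0, 1\].
#' @param dt frame interval (s).
#' @param n_steps steps per trajectory.
#' @param n_traj number of trajectories.
#' @param seed integer root seed.
#' @return A [trajectory_ensemble()] with an attached `compartment` index
#'   per trajectory (the starting compartment row in
#'   `mesh$compartments`).
#' @export
simulate_meshwork_confined_tracks <- function(mesh, diffusivity = 0.19,
                                              hop_probability = 0.05, dt = 0.02,
                                              n_steps = 100, n_traj = 1, seed = 1) {
  stopifnot(inherits(mesh, "meshwork_model"))
  if (!is.finite(hop_probability) || hop_probability < 0 || hop_probability > 1)
    stop("invalid-parameter: hop_probability must lie in [0, 1]", call. = FALSE)
  comp <- mesh$compartments
  if (!nrow(comp)) stop("invalid-parameter: degenerate meshwork", call. = FALSE)
  rects <- as.matrix(comp[, c("xmin", "xmax", "ymin", "ymax")])
  region <- c(0, mesh$region[1], 0, mesh$region[2])
  sigma <- sqrt(2 * diffusivity * dt)
  seeds <- split_seeds(seed, n_traj)
  times <- (0:n_steps) * dt
  trajs <- vector("list", n_traj)
  start_comp <- integer(n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(seeds[i])
    rc <- sample.int(nrow(rects), 1, prob = comp$area_um2)
    x0 <- runif(1, rects[rc, 1], rects[rc, 2])
    y0 <- runif(1, rects[rc, 3], rects[rc, 4])
    path <- cpp_mesh_confined_walk(rects, rc - 1L, x0, y0, hop_probability,
                                   sigma, n_steps, region)
    trajs[[i]] <- trajectory(sprintf("mesh_%04d", i), times, path)
    start_comp[i] <- rc
  }
  ens <- trajectory_ensemble(trajs, frame_interval = dt)
  attr(ens, "start_compartment") <- start_comp
  ens
}
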