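#' Load and validate a study configuration
#'
#' A study configuration is a plain named list (or a YAML file containing
#' one) with a `seed`, an output directory, simulator blocks and analysis
#' settings. Unknown keys are errors (fail-fast), so typos cannot silently
#' change a study.
#'
#' @param config path to a YAML file, or a named list.
#' @param kind "dynamics" or "meshwork"; controls the allowed blocks.
#' @return The validated configuration list (class `study_config`).
#' @export
study_config <- function(config, kind = c("dynamics", "meshwork")) {
  kind <- match.arg(kind)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config-error: configuration must be a list", call. = FALSE)
  allowed_top <- c("seed", "out_dir", "blocks", "analysis")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown))
    stop("config-error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) stop("config-error: missing field: seed", call. = FALSE)
  allowed_blocks <- if (kind == "dynamics") {
    c("fbm", "brownian", "percolation", "fences")
  } else c("meshwork", "localizations", "render", "segmentation",
           "boxcount", "fractal_oracle", "tracks", "msd_vs_distance")
  unknown <- setdiff(names(config$blocks), allowed_blocks)
  if (length(unknown))
    stop("config-error: unknown block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!length(config$blocks))
    stop("config-error: no blocks configured", call. = FALSE)
  config$kind <- kind
  class(config) <- c("study_config", "list")
  config
}

config_fingerprint <- function(config) {
  unclass(config)
  txt <- paste(deparse(config[setdiff(names(config), "kind")]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 0xFFFFFFFF)
}

new_report <- function(config, metrics, files) {
  structure(list(metrics = metrics, files = files,
                 provenance = list(seed = config$seed,
                                   config_hash = config_fingerprint(config),
                                   version = as.character(utils::packageVersion("cortexmesh")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$provenance$seed, "\n")
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (is.numeric(v) && length(v) == 1) cat(" ", nm, "=", signif(v, 5), "\n")
  }
  invisible(x)
}

#' Write a study report (with provenance) as JSON
#' @param report a `study_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run a trajectory-dynamics study
#'
#' Simulates each configured random-walk block, computes the
#' ensemble-averaged TA-MSD, its anomalous-exponent fit and the
#' lag-resolved turning-angle distributions, and writes per-block CSV/JSON
#' outputs plus a report. Deterministic given `seed`.
#'
#' Block parameters (each block is a list): `fbm`: hurst, n_steps, n_traj;
#' `brownian`: diffusivity, n_steps, n_traj; `percolation`: side,
#' obstacle_fraction, n_steps, n_traj, steps_per_frame, start; `fences`:
#' compartment_side, hop_probability, diffusivity, n_steps, n_traj.
#' Analysis settings: `lags` (seconds), `bin_width` (degrees),
#' `fit_range` (seconds).
#'
#' @param config a [study_config()] (or list/path coercible to one).
#' @return A `study_report`; metrics include per-block `alpha_<name>`,
#'   `angle_mode_<name>` and `lag_invariance_<name>`.
#' @export
run_dynamics_study <- function(config) {
  config <- study_config(config, "dynamics")
  out_dir <- config$out_dir %||% tempfile("dynamics_study_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  lags <- config$analysis$lags %||% c(0.02, 0.04, 0.1, 0.2, 0.5, 1.0)
  bw <- config$analysis$bin_width %||% 5
  metrics <- list(); files <- character(0)
  for (nm in names(config$blocks)) {
    b <- config$blocks[[nm]]
    ens <- switch(nm,
      fbm = simulate_fbm(hurst = b$hurst, n_steps = b$n_steps %||% 512,
                         n_traj = b$n_traj %||% 500, seed = seed),
      brownian = simulate_brownian(diffusivity = b$diffusivity %||% 0.19,
                                   n_steps = b$n_steps %||% 512,
                                   n_traj = b$n_traj %||% 500, seed = seed),
      percolation = {
        world <- build_obstacle_lattice(b$side %||% 256,
                                        b$obstacle_fraction,
                                        b$lattice_constant %||% 0.01, seed = seed)
        simulate_obstructed_walk(world, b$n_steps %||% 512,
                                 b$n_traj %||% 500, seed = seed,
                                 steps_per_frame = b$steps_per_frame %||% 1,
                                 start = b$start %||% "vacant")
      },
      fences = {
        world <- fence_world(b$compartment_side %||% 0.4,
                             b$hop_probability %||% 0.05,
                             b$diffusivity %||% 0.19)
        simulate_fenced_diffusion(world, b$n_steps %||% 512,
                                  b$n_traj %||% 500, seed = seed)
      })
    msd <- ensemble_ta_msd(ens, max_lag = config$analysis$max_lag %||% NULL)
    fit <- fit_anomalous_exponent(msd, config$analysis$fit_range %||% NULL)
    dists <- angle_distribution(ens, lags, bin_width = bw)
    msd_file <- file.path(out_dir, paste0("msd_", nm, ".csv"))
    write.csv(as.data.frame(msd), msd_file, row.names = FALSE)
    ang_file <- file.path(out_dir, paste0("angles_", nm, ".csv"))
    ang_df <- do.call(rbind, lapply(dists, function(d) {
      nb <- length(d$density)
      data.frame(lag_s = d$lag, bin_left_deg = d$bin_edges[1:nb],
                 bin_right_deg = d$bin_edges[2:(nb + 1)],
                 density_per_deg = d$density)
    }))
    write.csv(ang_df, ang_file, row.names = FALSE)
    files <- c(files, msd_file, ang_file)
    metrics[[paste0("alpha_", nm)]] <- fit$exponent
    metrics[[paste0("angle_mode_", nm)]] <- as.numeric(angle_mode(dists[[1]]))
    metrics[[paste0("lag_invariance_", nm)]] <- lag_invariance_statistic(dists)
  }
  report <- new_report(config, metrics, files)
  write_report(report, file.path(out_dir, "report.json"))
  report
}

#' Run a meshwork morphometry study
#'
#' Generates a fragmentation meshwork, samples localizations, renders a
#' reconstruction, segments compartments by watershed, fits the
#' log-normal area law and the perimeter-area scaling, and measures the
#' box-counting dimension; optionally adds a known-dimension fractal
#' oracle and a meshwork-confined track block with the distance-resolved
#' MSD analysis.
#'
#' @param config a [study_config()] for kind "meshwork". Blocks:
#'   `meshwork` (region, n_generations, min_area), `localizations`
#'   (linear_density, precision_mean, precision_sd, n_frames), `render`
#'   (pixel_size, blur_sd), `segmentation` (tolerance, min_area),
#'   `boxcount` (offsets), `fractal_oracle` (kind, size), `tracks`
#'   (diffusivity, hop_probability, n_steps, n_traj), `msd_vs_distance`
#'   (threshold, distance_bins).
#' @return A `study_report` with recovered and ground-truth log-normal
#'   parameters, perimeter-area fit, actin coverage and fractal dimension.
#' @export
run_meshwork_study <- function(config) {
  config <- study_config(config, "meshwork")
  if (is.null(config$blocks$meshwork))
    stop("config-error: missing block: meshwork", call. = FALSE)
  out_dir <- config$out_dir %||% tempfile("meshwork_study_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  b <- config$blocks
  mesh <- generate_fragmentation_meshwork(
    region = unlist(b$meshwork$region %||% c(20, 20)),
    n_generations = b$meshwork$n_generations %||% 11,
    min_area = b$meshwork$min_area %||% 0.01, seed = seed)
  locs <- meshwork_to_localizations(
    mesh, linear_density = b$localizations$linear_density %||% 500,
    precision_mean = b$localizations$precision_mean %||% 20,
    precision_sd = b$localizations$precision_sd %||% 8,
    n_frames = b$localizations$n_frames %||% 100, seed = seed + 1)
  img <- render_localizations(locs, pixel_size = b$render$pixel_size %||% 10,
                              blur_sd = b$render$blur_sd %||% 10)
  seg <- watershed_compartments(img,
                                tolerance = b$segmentation$tolerance %||% NULL,
                                min_area = b$segmentation$min_area %||% 0.005)
  true_fit <- fit_lognormal_areas(mesh$compartments$area_um2)
  rec_fit <- fit_lognormal_areas(seg$compartments$area_um2)
  pa <- perimeter_area_scaling(seg)
  bc <- box_count_dimension(mesh_image(seg$actin_mask * 1, img$pixel_size),
                            offsets = isTRUE(b$boxcount$offsets))
  comp_file <- file.path(out_dir, "compartments.csv")
  write.csv(seg$compartments, comp_file, row.names = FALSE)
  metrics <- list(
    n_compartments = nrow(seg$compartments),
    mu_log_true = true_fit$mu_log, sigma_log_true = true_fit$sigma_log,
    mu_log_recovered = rec_fit$mu_log, sigma_log_recovered = rec_fit$sigma_log,
    lognormal_gof_p = rec_fit$gof_p,
    pa_exponent = pa$exponent, pa_prefactor = pa$prefactor,
    pa_pearson_log = pa$pearson_log,
    actin_coverage = seg$actin_coverage,
    meshwork_actin_fraction = seg$meshwork_actin_fraction,
    fractal_dimension = bc$fractal_dimension)
  files <- comp_file
  if (!is.null(b$fractal_oracle)) {
    fr <- make_reference_fractals(b$fractal_oracle$kind %||% "sierpinski_carpet",
                                  b$fractal_oracle$size %||% 2187, seed = seed)
    metrics$oracle_fractal_dimension <-
      box_count_dimension(fr)$fractal_dimension
  }
  if (!is.null(b$tracks)) {
    ens <- simulate_meshwork_confined_tracks(
      mesh, diffusivity = b$tracks$diffusivity %||% 0.19,
      hop_probability = b$tracks$hop_probability %||% 0.05,
      n_steps = b$tracks$n_steps %||% 200, n_traj = b$tracks$n_traj %||% 100,
      seed = seed + 2)
    thr <- b$msd_vs_distance$threshold %||% seg$threshold
    db <- msd_vs_actin_distance(ens, img, threshold = thr,
                                distance_bins = unlist(b$msd_vs_distance$distance_bins %||%
                                                         seq(0, 500, 50)))
    db_file <- file.path(out_dir, "msd_vs_distance.csv")
    write.csv(data.frame(bin_left_nm = head(db$bin_edges, -1),
                         bin_right_nm = tail(db$bin_edges, -1),
                         msd_um2 = db$msd_um2, sem = db$sem, n = db$n_segments),
              db_file, row.names = FALSE)
    files <- c(files, db_file)
    ok <- db$n_segments > 0
    centers <- (head(db$bin_edges, -1) + tail(db$bin_edges, -1))[ok] / 2
    metrics$msd_distance_spearman <-
      suppressWarnings(cor(centers, db$msd_um2[ok], method = "spearman"))
  }
  report <- new_report(config, metrics, files)
  write_report(report, file.path(out_dir, "report.json"))
  report
}
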