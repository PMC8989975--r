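#' Run an end-to-end analysis pipeline from a configuration
#'
#' Chains the stages of one of the two acquisition types, writing artifacts
#' and a machine-readable JSON report to `out_dir`:
#'
#' * `mode = "fus"`: simulate a functional acquisition (block-streamed),
#'   SVD-filter and form the Power Doppler series, fit the GLM activation
#'   map, extract the ROI and compute the percent blood-volume trace.
#'   Report: number of significant pixels, max Z, `dbv_stim`, `dbv_bl`.
#' * `mode = "ulm"`: simulate a microbubble acquisition, filter, localize,
#'   link tracks, compute velocities and render the super-resolved maps.
#'   Report: number of localizations and tracks, speed quantiles.
#' * `mode = "stats"`: read records from `config$records_csv`, apply the
#'   signed square root, fit the mixed model and test the fixed effect.
#'
#' All randomness derives from the single `seed`; the report carries the
#' package version, the full parameter set and summary statistics, so that
#' identical configurations and seeds give identical reports apart from the
#' `timestamp` field.
#'
#' @param config A named list (see the fields above) or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed overriding `config$seed`.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$mode)) {
    stop("config must be a list (or YAML file) with a `mode` field", call. = FALSE)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("fusulm")),
    mode = config$mode, seed = seed, parameters = config,
    timestamp = format(Sys.time(), tz = "UTC"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (config$mode == "fus") {
    p <- config$paradigm %||% "corneal_mech"
    paradigm <- run_stage("paradigm", paradigm_preset(p, dt = config$dt %||% 0.1))
    cfg <- run_stage("config", {
      n_blocks <- as.integer(paradigm$total_duration /
                               ((config$block_size %||% 200) / (config$framerate %||% 500)))
      config_fus(n_blocks = n_blocks,
                 block_size = as.integer(config$block_size %||% 200),
                 framerate = config$framerate %||% 500,
                 depth_mm = config$depth_mm %||% 12,
                 width_mm = config$width_mm %||% 12.8,
                 pixel_dz = config$pixel_dz %||% 0.1,
                 pixel_dx = config$pixel_dx %||% 0.1)
    })
    mask <- matrix(FALSE, cfg$n_z, cfg$n_x)
    mc <- config$mask_center %||% c(round(cfg$n_z / 2), round(cfg$n_x / 3))
    mr <- config$mask_halfwidth %||% 3
    mask[(mc[1] - mr):(mc[1] + mr), (mc[2] - mr):(mc[2] + mr)] <- TRUE
    sim <- run_stage("simulate", simulate_functional_pd(
      cfg, activation_mask = mask,
      amplitude = config$amplitude %||% 0.10, paradigm = paradigm,
      tissue_rank = config$tissue_rank %||% 5,
      tissue_to_blood_db = config$tissue_to_blood_db %||% 40,
      noise_db = config$noise_db %||% -20,
      seed = seed, n_remove = config$n_remove %||% 60))
    design <- run_stage("design", build_design(
      paradigm, hrf_params(), dim(sim$pd$images)[3], sim$pd$frame_interval))
    map <- run_stage("map", glm_fit(sim$pd, design,
                                    alpha = config$alpha %||% 0.05))
    roi <- run_stage("roi", extract_roi(map))
    dbv <- run_stage("dbv", delta_bv(sim$pd, roi, paradigm))
    write_pd(sim$pd, file.path(out_dir, "pd.tif"))
    write_dbv(dbv, file.path(out_dir, "dbv.csv"))
    report$summary <- list(
      n_significant = sum(map$mask), max_z = max(map$z),
      roi_px = sum(roi$mask),
      dbv_stim = attr(dbv, "dbv_stim"), dbv_bl = attr(dbv, "dbv_bl"),
      true_dbv_stim = sim$truth$expected_dbv_stim)
  } else if (config$mode == "ulm") {
    cfg <- run_stage("config", config_ulm(
      n_blocks = as.integer(config$n_blocks %||% 10),
      depth_mm = config$depth_mm %||% 6.4,
      width_mm = config$width_mm %||% 6.4))
    vessels <- run_stage("vessels", default_vessels(cfg, config$speeds_mm_s %||% c(10, 15, 20)))
    sim <- run_stage("simulate", simulate_bubble_stack(
      cfg, vessels, bubbles_per_frame = config$bubbles_per_frame %||% 0.05,
      noise_db = config$noise_db %||% -40, seed = seed))
    locs <- run_stage("localize", ulm_localize(
      sim$stack, min_intensity = config$min_intensity %||% 0.25,
      n_remove = config$n_remove %||% 10))
    max_link <- config$max_link_mm %||%
      (1.5 * max(vapply(vessels, `[[`, numeric(1), "flow_speed")) / cfg$framerate)
    tracks <- run_stage("link", link_tracks(locs, max_link_mm = max_link,
                                            min_length = config$min_length %||% 4))
    tracks <- run_stage("velocity", track_velocities(tracks, cfg$framerate))
    maps <- run_stage("render", render_maps(tracks, cfg,
                                            pitch_um = config$pitch_um %||% 6.5))
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    sq <- stats::quantile(tracks$speed, c(0.1, 0.5, 0.9), na.rm = TRUE)
    report$summary <- list(
      n_localizations = nrow(locs), n_tracks = dplyr::n_distinct(tracks$track_id),
      speed_q10 = unname(sq[1]), speed_median = unname(sq[2]),
      speed_q90 = unname(sq[3]))
  } else if (config$mode == "stats") {
    records <- run_stage("read", readr::read_csv(config$records_csv,
                                                 show_col_types = FALSE))
    records$y <- signed_sqrt(records[[config$response %||% "y"]])
    fit <- run_stage("fit", fit_lmm(records, form = config$form %||% "one_level"))
    ft <- test_fixed_effect(fit)
    report$summary <- list(delta_hat = fit$delta_hat,
                           sigma2 = as.list(fit$sigma2),
                           f_statistic = ft$statistic, p_value = ft$p.value)
  } else {
    stop(sprintf("unknown pipeline mode '%s'", config$mode), call. = FALSE)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Default synthetic vessel geometry
#'
#' Three smooth quasi-horizontal vessels spanning the field of view — two
#' flowing one way and one the other, emulating the descending-vein /
#' ascending-artery contrast of a sensory ganglion — at the given speeds.
#'
#' @param config A `fus_config`.
#' @param speeds_mm_s Flow speeds, one per vessel (recycled to 3).
#' @return List of `fus_vessel`.
#' @export
default_vessels <- function(config, speeds_mm_s = c(10, 15, 20)) {
  speeds <- rep(speeds_mm_s, length.out = 3)
  zlev <- config$depth_mm * c(0.3, 0.5, 0.7)
  xr <- c(0.08 * config$width_mm, 0.92 * config$width_mm)
  mk <- function(z0, speed, dir, wig) {
    xs <- seq(xr[1], xr[2], length.out = 12)
    zs <- z0 + wig * config$depth_mm * sin(seq(0, pi, length.out = 12))
    vessel_path(cbind(zs, xs), flow_speed = speed, radius = 0.02,
                direction = dir)
  }
  list(mk(zlev[1], speeds[1], 1, 0.04),
       mk(zlev[2], speeds[2], -1, -0.03),
       mk(zlev[3], speeds[3], 1, 0.05))
}
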