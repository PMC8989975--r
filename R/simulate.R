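#' Vessel path for the microbubble simulator
#'
#' A vessel is a polyline in the imaging plane along which microbubbles
#' advect at a constant speed. Vertices are `(z, x)` positions in mm;
#' `direction = -1` reverses the travel direction along the polyline. The
#' vessel `radius` jitters each bubble perpendicular to the local tangent,
#' standing in for a finite lumen.
#'
#' @param vertices Two-column matrix or data frame of `(z, x)` vertices (mm),
#'   at least two rows.
#' @param flow_speed Bubble speed along the path (mm/s), > 0.
#' @param radius Lumen radius (mm), > 0.
#' @param direction `+1` (vertex order) or `-1` (reversed).
#' @return An object of class `fus_vessel`.
#' @export
vessel_path <- function(vertices, flow_speed, radius = 0.02, direction = 1) {
  v <- as.matrix(vertices)
  if (nrow(v) < 2L || ncol(v) != 2L) {
    stop("`vertices` must be a 2-column (z, x) matrix with >= 2 rows", call. = FALSE)
  }
  assert_scalar_num(flow_speed, "flow_speed", 0, strict = TRUE)
  assert_scalar_num(radius, "radius", 0, strict = TRUE)
  if (!direction %in% c(-1, 1)) stop("`direction` must be +1 or -1", call. = FALSE)
  if (direction == -1) v <- v[nrow(v):1, , drop = FALSE]
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("degenerate (zero-length) polyline segment", call. = FALSE)
  structure(
    list(vertices = v, flow_speed = flow_speed, radius = radius,
         direction = direction, cumlen = c(0, cumsum(len)),
         tangents = seg / len),
    class = "fus_vessel")
}

# position and unit tangent at arc length s along a vessel
vessel_point <- function(vessel, s) {
  cl <- vessel$cumlen
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(vessel$tangents))
  p <- vessel$vertices[i, , drop = FALSE] +
    (s - cl[i]) * vessel$tangents[i, , drop = FALSE]
  list(pos = p, tan = vessel$tangents[i, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# functional (fUS) simulator
# ---------------------------------------------------------------------------

# Gaussian Doppler power spectrum over the n_t FFT bins of one block,
# normalised to unit total power. This is the second-order statistics of an
# ensemble of unresolved blood scatterers with mean Doppler shift
# `doppler_hz` and in-cell velocity dispersion giving spectral spread
# `spread_hz`.
blood_psd <- function(n_t, framerate, doppler_hz, spread_hz) {
  f <- (seq_len(n_t) - 1) / n_t * framerate
  f <- ifelse(f >= framerate / 2, f - framerate, f)  # wrap to [-fs/2, fs/2)
  q <- exp(-(f - doppler_hz)^2 / (2 * spread_hz^2))
  q / sum(q)
}

# global (stack-wide) tissue model: `rank` separable space-time components,
# smooth random spatial fields times slow cosines; exactly rank <= `rank`
# inside every block. Component amplitudes decay by `decay_db` dB per rank,
# emulating the smoothly decaying singular spectrum of in vivo tissue
# clutter.
tissue_model <- function(config, rank, seed, decay_db = 6) {
  if (rank == 0) return(NULL)
  set.seed(stage_seed(seed, "tissue"))
  n_z <- config$n_z; n_x <- config$n_x
  zs <- seq(0, 1, length.out = n_z); xs <- seq(0, 1, length.out = n_x)
  # smooth random fields from a low-order 2-D cosine basis; the basis order
  # grows with the requested rank so the spatial maps stay linearly
  # independent
  ord <- ceiling(sqrt(rank + 2)) - 1
  maps <- matrix(0, n_z * n_x, rank)
  for (r in seq_len(rank)) {
    m <- matrix(0, n_z, n_x)
    for (p in 0:ord) for (q in 0:ord) {
      m <- m + stats::rnorm(1) * outer(cos(pi * p * zs), cos(pi * q * xs))
    }
    maps[, r] <- as.vector(m) / sqrt(mean(m^2))
  }
  # temporal frequencies span the quasi-DC to cardiac-harmonic range; the
  # oscillating components complete at least one cycle per 0.4-s processing
  # block (>= 2.5 Hz), keeping all components linearly independent inside a
  # block so the clutter subspace has full numerical rank there
  freq <- if (rank == 1) 0.02 else {
    c(0.02, seq(2.5, 25, length.out = rank - 1) +
        stats::runif(rank - 1, -0.3, 0.3))
  }
  list(maps = maps,
       amps = 10^(-decay_db * (seq_len(rank) - 1) / 20),
       freq = freq,
       phase = stats::runif(rank, 0, 2 * pi),
       cphase = exp(1i * stats::runif(rank, 0, 2 * pi)))
}

# temporal tissue basis at the given frame times (rank x n_t)
tissue_basis <- function(tm, times, complex_mode) {
  u <- t(vapply(seq_along(tm$freq), function(r) {
    cos(2 * pi * tm$freq[r] * times + tm$phase[r])
  }, numeric(length(times))))
  if (!is.matrix(u)) u <- matrix(u, nrow = length(tm$freq))
  if (complex_mode) u <- u * tm$cphase
  tm$amps * u
}

# synthesize one block (n_px x n_t matrix) of the functional acquisition
fus_synth_block <- function(b, cfg, env) {
  B <- cfg$block_size
  n_px <- cfg$n_z * cfg$n_x
  times <- ((b - 1) * B + seq_len(B) - 0.5) / cfg$framerate
  out <- matrix(if (env$complex_mode) 0i else 0, n_px, B)
  if ("blood" %in% env$components) {
    set.seed(stage_seed(env$seed, paste0("blood_", b)))
    W <- matrix(complex(real = stats::rnorm(B * n_px),
                        imaginary = stats::rnorm(B * n_px)) / sqrt(2), B, n_px)
    s <- stats::mvfft(W * sqrt(env$q), inverse = TRUE)   # unit-power process
    s <- t(s)
    if (!env$complex_mode) s <- Re(s) * sqrt(2)
    r_t <- if (is.null(env$r_of_t)) rep(0, B) else env$r_of_t(times)
    gain <- sqrt(env$base_vec) *
      sqrt(1 + env$amplitude * outer(env$mask_vec, r_t))
    out <- out + gain * s
  }
  if (!is.null(env$tissue) && "tissue" %in% env$components) {
    u <- tissue_basis(env$tissue, times, env$complex_mode)
    out <- out + env$tissue_amp * (env$tissue$maps %*% u)
  }
  if ("noise" %in% env$components && env$noise_sd > 0) {
    set.seed(stage_seed(env$seed, paste0("noise_", b)))
    if (env$complex_mode) {
      out <- out + matrix(complex(real = stats::rnorm(B * n_px),
                                  imaginary = stats::rnorm(B * n_px)),
                          n_px, B) * env$noise_sd / sqrt(2)
    } else {
      out <- out + matrix(stats::rnorm(B * n_px, sd = env$noise_sd), n_px, B)
    }
  }
  out
}

# shared setup for the functional simulator
fus_synth_env <- function(config, baseline_map, activation_mask, amplitude,
                          paradigm, hrf, tissue_rank, tissue_to_blood_db,
                          tissue_decay_db, noise_db, doppler_hz, spread_hz,
                          seed, complex, components) {
  n_z <- config$n_z; n_x <- config$n_x
  if (is.null(baseline_map)) baseline_map <- matrix(1, n_z, n_x)
  if (is.null(activation_mask)) activation_mask <- matrix(FALSE, n_z, n_x)
  if (!all(dim(baseline_map) == c(n_z, n_x))) {
    stop("`baseline_map` shape does not match the configured grid", call. = FALSE)
  }
  if (!all(dim(activation_mask) == c(n_z, n_x))) {
    stop("`activation_mask` shape does not match the configured grid", call. = FALSE)
  }
  if (any(baseline_map < 0)) stop("`baseline_map` must be nonnegative", call. = FALSE)
  if (amplitude <= -1) stop("`amplitude` must be > -1", call. = FALSE)
  if (tissue_rank < 0 || tissue_rank >= config$block_size) {
    stop("`tissue_rank` must satisfy 0 <= tissue_rank < block_size", call. = FALSE)
  }
  blood_rms <- sqrt(mean(baseline_map))
  r_of_t <- NULL
  if (!is.null(paradigm) && amplitude != 0) {
    rf <- response_fine(paradigm, hrf)
    r_of_t <- function(tt) stats::approx(rf$time, rf$r, xout = tt, rule = 2)$y
  }
  list(
    seed = seed, complex_mode = complex, components = components,
    base_vec = as.vector(baseline_map), mask_vec = as.numeric(activation_mask),
    amplitude = amplitude, r_of_t = r_of_t,
    q = blood_psd(config$block_size, config$framerate, doppler_hz, spread_hz),
    tissue = tissue_model(config, tissue_rank, seed, tissue_decay_db),
    tissue_amp = db_to_amp(tissue_to_blood_db) * blood_rms,
    noise_sd = db_to_amp(noise_db) * blood_rms,
    baseline_map = baseline_map, activation_mask = activation_mask)
}

# ground truth carried alongside a functional simulation
fus_truth <- function(config, env, paradigm, hrf, amplitude, seed) {
  fi <- config$block_size / config$framerate
  n_b <- config$n_blocks
  t_pd <- (seq_len(n_b) - 0.5) * fi
  r_pd <- if (is.null(env$r_of_t)) rep(0, n_b) else env$r_of_t(t_pd)
  expected_dbv_stim <- NA_real_
  stim <- rep(FALSE, n_b)
  if (!is.null(paradigm)) {
    stim <- classify_frames(paradigm, n_b, fi)
    if (any(stim) && any(!stim)) {
      r_bl <- mean(r_pd[!stim])
      expected_dbv_stim <-
        100 * amplitude * (mean(r_pd[stim]) - r_bl) / (1 + amplitude * r_bl)
    }
  }
  list(activation_mask = env$activation_mask, amplitude = amplitude,
       baseline_map = env$baseline_map, r_pd = r_pd, stim_frames = stim,
       expected_dbv_stim = expected_dbv_stim, seed = seed)
}

#' Simulate a functional ultrafast acquisition
#'
#' Generates a seeded, ground-truth-annotated ultrafast frame stack with the
#' three additive components the clutter filter assumes:
#'
#' * **tissue**: `tissue_rank` separable space-time components (smooth random
#'   spatial fields times slow oscillations), `tissue_to_blood_db` decibels
#'   above the blood signal in amplitude (20*log10 convention) — the
#'   quasi-low-rank clutter the SVD filter removes;
#' * **blood**: a complex Gaussian scatterer-ensemble process per pixel with
#'   a Gaussian Doppler spectrum (mean shift `doppler_hz`, spread
#'   `spread_hz`), whose expected power follows
#'   `baseline_map * (1 + amplitude * r(t))` inside `activation_mask` and
#'   `baseline_map` outside, `r(t)` being the paradigm convolved with the
#'   HRF and peak-normalised;
#' * **noise**: white complex Gaussian, `noise_db` decibels relative to the
#'   blood amplitude.
#'
#' Identical `seed` gives bitwise-identical output, and each component's
#' randomness is drawn from its own derived stream, so generating components
#' separately (via `components`) and summing reproduces the composite
#' exactly.
#'
#' @param config A `fus_config`; the stack has
#'   `block_size * n_blocks` frames.
#' @param baseline_map Nonnegative `(n_z, n_x)` blood power map (default
#'   uniform 1).
#' @param activation_mask Logical `(n_z, n_x)` map of responding pixels.
#' @param amplitude Fractional blood-volume response (e.g. 0.10 for 10%);
#'   must be > -1.
#' @param paradigm A `fus_paradigm` (or `NULL` for a resting acquisition).
#' @param hrf A `fus_hrf`.
#' @param tissue_rank Number of tissue components, `0 <= rank < block_size`.
#' @param tissue_to_blood_db Tissue-to-blood amplitude ratio in dB.
#' @param tissue_decay_db Amplitude decay of successive tissue components in
#'   dB per rank (the smoothly decaying clutter singular spectrum).
#' @param noise_db Noise-to-blood amplitude ratio in dB (`-Inf` disables).
#' @param doppler_hz,spread_hz Blood Doppler spectrum centre and spread (Hz).
#'   Defaults correspond to ~10 mm/s flow at a 15-MHz transmit and the
#'   transit-time broadening of a 100-um resolution cell.
#' @param seed Integer seed.
#' @param complex Complex IQ frames (default) or real-valued frames.
#' @param components Which components to include (for composition tests).
#' @return A list with `stack` (a `fus_stack`) and `truth` (activation mask,
#'   amplitude, per-frame expected response, frame classification and the
#'   expected Power-Doppler-level `expected_dbv_stim` in percent).
#' @export
simulate_functional_stack <- function(config, baseline_map = NULL,
                                      activation_mask = NULL, amplitude = 0,
                                      paradigm = NULL, hrf = hrf_params(),
                                      tissue_rank = 5, tissue_to_blood_db = 40,
                                      tissue_decay_db = 6,
                                      noise_db = -20, doppler_hz = 250,
                                      spread_hz = 130, seed = 1,
                                      complex = TRUE,
                                      components = c("tissue", "blood", "noise")) {
  env <- fus_synth_env(config, baseline_map, activation_mask, amplitude,
                       paradigm, hrf, tissue_rank, tissue_to_blood_db,
                       tissue_decay_db, noise_db, doppler_hz, spread_hz,
                       seed, complex, components)
  n_t <- config$block_size * config$n_blocks
  frames <- array(if (complex) 0i else 0, dim = c(config$n_z, config$n_x, n_t))
  for (b in seq_len(config$n_blocks)) {
    blk <- fus_synth_block(b, config, env)
    frames[, , ((b - 1) * config$block_size + 1):(b * config$block_size)] <-
      uncasorati(blk, c(config$n_z, config$n_x))
  }
  list(stack = frame_stack(frames, config),
       truth = fus_truth(config, env, paradigm, hrf, amplitude, seed))
}

#' Simulate and filter a functional acquisition block by block
#'
#' Equivalent to [simulate_functional_stack()] followed by
#' [process_stack()], but synthesises, SVD-filters and integrates one block
#' at a time so that long acquisitions (hundreds of blocks) never hold the
#' full ultrafast stack in memory. Uses exactly the same per-block random
#' streams as the full-stack generator.
#'
#' @inheritParams simulate_functional_stack
#' @param n_remove Singular vectors removed per block.
#' @return A list with `pd` (a `fus_pd`) and `truth`.
#' @export
simulate_functional_pd <- function(config, baseline_map = NULL,
                                   activation_mask = NULL, amplitude = 0,
                                   paradigm = NULL, hrf = hrf_params(),
                                   tissue_rank = 5, tissue_to_blood_db = 40,
                                   tissue_decay_db = 6,
                                   noise_db = -20, doppler_hz = 250,
                                   spread_hz = 130, seed = 1, complex = TRUE,
                                   n_remove = 60,
                                   components = c("tissue", "blood", "noise")) {
  env <- fus_synth_env(config, baseline_map, activation_mask, amplitude,
                       paradigm, hrf, tissue_rank, tissue_to_blood_db,
                       tissue_decay_db, noise_db, doppler_hz, spread_hz,
                       seed, complex, components)
  n_b <- config$n_blocks
  images <- array(0, dim = c(config$n_z, config$n_x, n_b))
  grid <- c(config$n_z, config$n_x)
  for (b in seq_len(n_b)) {
    blk <- uncasorati(fus_synth_block(b, config, env), grid)
    images[, , b] <- power_doppler(svd_filter_block(blk, n_remove))
  }
  pd <- pd_series(images, config$block_size / config$framerate, config,
                  n_removed = n_remove)
  list(pd = pd, truth = fus_truth(config, env, paradigm, hrf, amplitude, seed))
}

# ---------------------------------------------------------------------------
# microbubble (ULM) simulator
# ---------------------------------------------------------------------------

#' Simulate a microbubble acquisition
#'
#' Generates an ultrafast movie of point-like microbubbles advecting along
#' vessel paths under a Gaussian point-spread function, over low-rank tissue
#' clutter and white noise. Bubbles enter each vessel as a Poisson process
#' (`bubbles_per_frame` expected arrivals per frame per vessel), advance by
#' `flow_speed / framerate` each frame, are jittered across the lumen by the
#' vessel radius, and leave the simulation at the end of the path. Bubble
#' amplitudes are drawn uniformly in `[0.5, 1.5]` around a unit mean;
#' `tissue_to_bubble_db` and `noise_db` are amplitude ratios (20*log10)
#' relative to that unit bubble peak.
#'
#' @param config A `fus_config` (ULM preset: 400-frame blocks at 1000 Hz).
#' @param vessels Non-empty list of [vessel_path()] objects; every path
#'   (inflated by its radius) must lie inside the imaging grid.
#' @param bubbles_per_frame Expected arrivals per frame per vessel.
#' @param psf_sigma_mm Gaussian point-spread-function scale (mm), > 0.
#' @param min_spacing_mm Minimum along-vessel spacing between successive
#'   bubbles (mm); 0 restores a pure Poisson process.
#' @param tissue_rank,tissue_to_bubble_db,tissue_decay_db,noise_db
#'   Clutter/noise model as in [simulate_functional_stack()]. The defaults
#'   (rank 10, 3 dB/rank decay) keep every tissue component well above the
#'   bubble signal, so the standard 10-component cutoff removes exactly the
#'   tissue subspace — the regime the cutoff is calibrated for in vivo.
#' @param seed Integer seed.
#' @param complex Complex frames (each bubble carries a fixed random phase)
#'   or real-valued frames.
#' @return A list with `stack` (a `fus_stack`) and `truth`: a tibble of
#'   ground-truth tracks (`track_id`, `frame`, `z_mm`, `x_mm`, `vz`, `vx`)
#'   plus the seed.
#' @export
simulate_bubble_stack <- function(config, vessels, bubbles_per_frame = 0.002,
                                  psf_sigma_mm = 0.045, tissue_rank = 10,
                                  tissue_to_bubble_db = 30,
                                  tissue_decay_db = 3, noise_db = -40,
                                  min_spacing_mm = 0.4,
                                  seed = 1, complex = TRUE) {
  if (!is.list(vessels) || length(vessels) == 0) {
    stop("`vessels` must be a non-empty list of vessel_path objects", call. = FALSE)
  }
  stopifnot(all(vapply(vessels, inherits, logical(1), "fus_vessel")))
  assert_scalar_num(psf_sigma_mm, "psf_sigma_mm", 0, strict = TRUE)
  for (v in vessels) {
    lo <- apply(v$vertices, 2, min) - v$radius
    hi <- apply(v$vertices, 2, max) + v$radius
    if (lo[1] < 0 || lo[2] < 0 || hi[1] > config$depth_mm || hi[2] > config$width_mm) {
      stop("vessel path (including its radius) extends outside the imaging grid",
           call. = FALSE)
    }
  }
  n_t <- config$block_size * config$n_blocks
  n_z <- config$n_z; n_x <- config$n_x
  zc <- pixel_centers(n_z, config$pixel_dz)
  xc <- pixel_centers(n_x, config$pixel_dx)

  # --- bubble trajectories (ground truth) ---
  set.seed(stage_seed(seed, "bubbles"))
  recs <- list(); next_id <- 1L
  for (vi in seq_along(vessels)) {
    v <- vessels[[vi]]
    arrivals <- stats::rpois(n_t, bubbles_per_frame)
    birth <- rep(seq_len(n_t), arrivals)
    if (min_spacing_mm > 0 && length(birth) > 1) {
      # hard-core thinning: bubbles travel single file, so two arrivals in
      # the same vessel cannot be closer than the exclusion distance
      gap_frames <- min_spacing_mm / (v$flow_speed / config$framerate)
      keep_birth <- birth[1]
      for (bb in birth[-1]) {
        if (bb - keep_birth[length(keep_birth)] >= gap_frames) {
          keep_birth <- c(keep_birth, bb)
        }
      }
      birth <- keep_birth
    }
    if (length(birth) == 0) next
    L <- max(v$cumlen)
    for (bb in seq_along(birth)) {
      off <- stats::runif(1, -v$radius, v$radius)
      amp <- stats::runif(1, 0.5, 1.5)
      phase <- stats::runif(1, 0, 2 * pi)
      life <- floor(L / (v$flow_speed / config$framerate))
      fr <- birth[bb]:min(n_t, birth[bb] + life)
      s <- (fr - birth[bb]) * v$flow_speed / config$framerate
      keep <- s <= L
      fr <- fr[keep]; s <- s[keep]
      if (length(fr) == 0) next
      vp <- vessel_point(v, s)
      normal <- cbind(-vp$tan[, 2], vp$tan[, 1])
      pos <- vp$pos + off * normal
      recs[[length(recs) + 1L]] <- tibble::tibble(
        track_id = next_id, frame = fr,
        z_mm = pos[, 1], x_mm = pos[, 2],
        vz = v$flow_speed * vp$tan[, 1], vx = v$flow_speed * vp$tan[, 2],
        amp = amp, phase = phase)
      next_id <- next_id + 1L
    }
  }
  truth_tracks <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(track_id = integer(), frame = integer(), z_mm = numeric(),
                   x_mm = numeric(), vz = numeric(), vx = numeric(),
                   amp = numeric(), phase = numeric())

  # --- rendering ---
  frames <- array(if (complex) 0i else 0, dim = c(n_z, n_x, n_t))
  if (nrow(truth_tracks) > 0) {
    win <- ceiling(4 * psf_sigma_mm / min(config$pixel_dz, config$pixel_dx))
    byf <- split(truth_tracks, truth_tracks$frame)
    for (nm in names(byf)) {
      f <- as.integer(nm)
      sub <- byf[[nm]]
      img <- matrix(0i, n_z, n_x)
      for (k in seq_len(nrow(sub))) {
        iz <- which.min(abs(zc - sub$z_mm[k]))
        ix <- which.min(abs(xc - sub$x_mm[k]))
        zi <- max(1, iz - win):min(n_z, iz + win)
        xi <- max(1, ix - win):min(n_x, ix + win)
        blob <- outer(exp(-(zc[zi] - sub$z_mm[k])^2 / (2 * psf_sigma_mm^2)),
                      exp(-(xc[xi] - sub$x_mm[k])^2 / (2 * psf_sigma_mm^2)))
        img[zi, xi] <- img[zi, xi] +
          sub$amp[k] * exp(1i * sub$phase[k]) * blob
      }
      frames[, , f] <- img
    }
  }
  if (!complex) frames <- Re(frames)

  # --- tissue and noise ---
  tm <- tissue_model(config, tissue_rank, seed, tissue_decay_db)
  if (!is.null(tm)) {
    t_amp <- db_to_amp(tissue_to_bubble_db)
    for (b in seq_len(config$n_blocks)) {
      idx <- ((b - 1) * config$block_size + 1):(b * config$block_size)
      times <- (idx - 0.5) / config$framerate
      u <- tissue_basis(tm, times, complex)
      tb <- uncasorati(t_amp * (tm$maps %*% u), c(n_z, n_x))
      frames[, , idx] <- frames[, , idx] + tb
    }
  }
  n_sd <- db_to_amp(noise_db)
  if (n_sd > 0) {
    set.seed(stage_seed(seed, "ulm_noise"))
    if (complex) {
      frames <- frames + array(complex(real = stats::rnorm(length(frames)),
                                       imaginary = stats::rnorm(length(frames))),
                               dim = dim(frames)) * n_sd / sqrt(2)
    } else {
      frames <- frames + array(stats::rnorm(length(frames), sd = n_sd),
                               dim = dim(frames))
    }
  }
  list(stack = frame_stack(frames, config),
       truth = list(tracks = dplyr::select(truth_tracks, -"amp", -"phase"),
                    seed = seed))
}

# ---------------------------------------------------------------------------
# mixed-model records
# ---------------------------------------------------------------------------

#' Simulate nested blood-volume difference records
#'
#' Draws records from the nested random-effects models used for evoked
#' response statistics: `Y_ik = delta + R_i + W_ik` (one level) or
#' `Y_ijk = delta + R_i + A_ij + W_ijk` (two levels), with independent
#' zero-mean Gaussian rat, acquisition and residual terms.
#'
#' @param n_rats Number of rats.
#' @param n_acq Acquisitions per rat.
#' @param n_stim Stimulations per acquisition.
#' @param delta Fixed effect (the side difference).
#' @param sigma_rat,sigma_acq,sigma_res Standard deviations of the rat,
#'   acquisition and residual effects.
#' @param seed Integer seed.
#' @return Tibble with columns `rat`, `acquisition`, `stimulation`, `y`.
#' @export
simulate_dbv_records <- function(n_rats, n_acq = 1, n_stim = 1, delta = 0,
                                 sigma_rat = 0.5, sigma_acq = 0,
                                 sigma_res = 1, seed = 1) {
  set.seed(stage_seed(seed, "lmm"))
  g <- expand.grid(stimulation = seq_len(n_stim), acquisition = seq_len(n_acq),
                   rat = seq_len(n_rats))
  R <- stats::rnorm(n_rats, sd = sigma_rat)
  A <- matrix(stats::rnorm(n_rats * n_acq, sd = sigma_acq), n_rats, n_acq)
  y <- delta + R[g$rat] + A[cbind(g$rat, g$acquisition)] +
    stats::rnorm(nrow(g), sd = sigma_res)
  tibble::tibble(rat = factor(g$rat), acquisition = factor(g$acquisition),
                 stimulation = g$stimulation, y = y)
}
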