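# small builders shared across the suite

tiny_config <- function(n_blocks = 1, block = 20, nz = 8, nx = 8) {
  acquisition_config(framerate = 500, block_size = block, n_blocks = n_blocks,
                     pixel_dz = 0.1, pixel_dx = 0.1,
                     depth_mm = nz * 0.1, width_mm = nx * 0.1)
}

random_block <- function(nz = 8, nx = 8, nt = 20, complex = TRUE, seed = 1) {
  set.seed(seed)
  if (complex) {
    array(complex(real = rnorm(nz * nx * nt), imaginary = rnorm(nz * nx * nt)),
          dim = c(nz, nx, nt))
  } else {
    array(rnorm(nz * nx * nt), dim = c(nz, nx, nt))
  }
}

frob <- function(x) sqrt(sum(Mod(x)^2))

# brute-force minimum-cost assignment by permutation enumeration (n <= 6)
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf; bp <- NULL
  for (p in perms(seq_len(n))) {
    val <- sum(cost[cbind(seq_len(n), p)])
    if (val < best - 1e-12) { best <- val; bp <- p }
  }
  list(cost = best, perm = bp)
}

# match recovered track segments to ground-truth segments: for each truth
# segment (truth point with a successor), the best recovered segment starting
# within `radius` mm in the same frame; returns per-truth-segment relative
# speed error
match_segments <- function(tracks, truth, radius = 0.1) {
  seg <- as.data.frame(tracks)[!is.na(tracks$speed), ]
  truth <- as.data.frame(truth)
  last_frame <- tapply(truth$frame, truth$track_id, max)
  tseg <- truth[truth$frame < last_frame[as.character(truth$track_id)], ]
  tseg$speed_t <- sqrt(tseg$vz^2 + tseg$vx^2)
  m <- merge(tseg, seg, by = "frame", suffixes = c(".t", ""))
  m$dist <- sqrt((m$z_mm - m$z_mm.t)^2 + (m$x_mm - m$x_mm.t)^2)
  m <- m[m$dist < radius, ]
  key <- paste(m$track_id.t, m$frame)
  relerr <- abs(m$speed - m$speed_t) / m$speed_t
  err <- tapply(relerr, key, min)
  list(n_truth = nrow(tseg), n_recovered = length(err), err = as.numeric(err))
}

# independent frame classifier: a frame is "stim" iff any sample of its span
# falls inside a stimulation window (scan of the raw window definitions)
classify_frames_oracle <- function(paradigm, n, dt_f) {
  vapply(seq_len(n), function(b) {
    ts <- seq((b - 1) * dt_f, b * dt_f - paradigm$dt / 2, by = paradigm$dt)
    any(vapply(ts, function(t) {
      any(t >= paradigm$onsets - 1e-9 &
          t < paradigm$onsets + paradigm$durations - 1e-9)
    }, logical(1)))
  }, logical(1))
}
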