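#' Detect microbubbles in one filtered frame
#'
#' Candidate bubbles are pixels that are the strict maximum of their
#' `neighborhood x neighborhood` window and at least `min_intensity` bright
#' (on the magnitude image). Each candidate is refined to a sub-pixel
#' position; the default refinement fits a separable Gaussian through the
#' log-intensities of the centre pixel and its two axial neighbours
#' (log-parabola vertex), which is exact for a Gaussian point-spread
#' function; `refine = "centroid"` uses the intensity-weighted centroid over
#' the window instead.
#'
#' Maxima whose full window does not fit inside the frame (border pixels)
#' are not considered.
#'
#' When two bubbles lie within a few point-spread-function widths, the tail
#' of one contaminates the refinement stencil of the other and biases both
#' positions. With `deconflict = TRUE` (the default for Gaussian refinement
#' on complex frames) each detection's estimated coherent Gaussian is
#' subtracted from its neighbours' stencils and the refinement is repeated —
#' the usual remedy in high-density localization microscopy.
#'
#' @param frame Real or complex matrix `(n_z, n_x)` (one SVD-filtered
#'   frame).
#' @param min_intensity Detection threshold on the magnitude image.
#' @param neighborhood Odd window size in pixels (default 3).
#' @param pixel_dz,pixel_dx Grid spacing in mm.
#' @param refine `"gaussian"` (default) or `"centroid"`.
#' @param deconflict Subtract neighbouring detections' tails before the
#'   final refinement.
#' @return Tibble of localizations: `z_mm`, `x_mm`, `intensity`.
#' @export
detect_bubbles <- function(frame, min_intensity, neighborhood = 3L,
                           pixel_dz = 0.1, pixel_dx = 0.1,
                           refine = c("gaussian", "centroid"),
                           deconflict = TRUE) {
  refine <- match.arg(refine)
  img <- Mod(frame)
  d <- dim(img)
  h <- (neighborhood - 1L) %/% 2L
  if (neighborhood %% 2L != 1L || neighborhood < 3L) {
    stop("`neighborhood` must be an odd integer >= 3", call. = FALSE)
  }
  if (neighborhood > min(d)) {
    stop("`neighborhood` is larger than the frame", call. = FALSE)
  }
  cand <- which(img >= min_intensity)
  cand <- cand[((cand - 1L) %% d[1]) + 1L > h & ((cand - 1L) %% d[1]) + 1L <= d[1] - h &
               ((cand - 1L) %/% d[1]) + 1L > h & ((cand - 1L) %/% d[1]) + 1L <= d[2] - h]
  if (length(cand) == 0) {
    return(tibble::tibble(z_mm = numeric(), x_mm = numeric(), intensity = numeric()))
  }
  iz <- ((cand - 1L) %% d[1]) + 1L
  ix <- ((cand - 1L) %/% d[1]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    w <- img[(iz[k] - h):(iz[k] + h), (ix[k] - h):(ix[k] + h)]
    c0 <- w[h + 1L, h + 1L]
    w[h + 1L, h + 1L] <- -Inf
    mx <- max(w)
    if (c0 > mx) {
      keep[k] <- TRUE
    } else if (c0 == mx) {
      # plateau tie (e.g. a bubble exactly on a pixel boundary): keep only
      # the first tied pixel in column-major raster order
      ties <- which(w == mx)
      ti <- ((ties - 1L) %% neighborhood) + iz[k] - h
      tj <- ((ties - 1L) %/% neighborhood) + ix[k] - h
      keep[k] <- all((tj - 1L) * d[1] + ti > (ix[k] - 1L) * d[1] + iz[k])
    }
  }
  iz <- iz[keep]; ix <- ix[keep]
  if (length(iz) == 0) {
    return(tibble::tibble(z_mm = numeric(), x_mm = numeric(), intensity = numeric()))
  }
  zs <- xs <- sz <- numeric(length(iz))
  for (k in seq_along(iz)) {
    if (refine == "gaussian") {
      rz <- log_parabola_offset(img[iz[k] - 1L, ix[k]], img[iz[k], ix[k]],
                                img[iz[k] + 1L, ix[k]], curvature = TRUE)
      rx <- log_parabola_offset(img[iz[k], ix[k] - 1L], img[iz[k], ix[k]],
                                img[iz[k], ix[k] + 1L], curvature = TRUE)
      dz <- rz[1]; dx <- rx[1]
      sz[k] <- sqrt(max(mean(c(rz[2], rx[2])), 0.04))  # sigma in pixels
    } else {
      w <- img[(iz[k] - h):(iz[k] + h), (ix[k] - h):(ix[k] + h)]
      tot <- sum(w)
      dz <- sum(rowSums(w) * (-h:h)) / tot
      dx <- sum(colSums(w) * (-h:h)) / tot
    }
    zs[k] <- (iz[k] - 0.5 + dz) * pixel_dz
    xs[k] <- (ix[k] - 0.5 + dx) * pixel_dx
  }
  if (deconflict && refine == "gaussian" && length(iz) > 1) {
    # coherent neighbour-tail subtraction: model each neighbour as a complex
    # Gaussian anchored at its peak pixel, remove it from the 3-point
    # stencils, and refine again (two passes)
    fr <- frame
    zc_px <- zs / pixel_dz + 0.5   # continuous pixel coordinates
    xc_px <- xs / pixel_dx + 0.5
    for (pass in 1:2) {
      for (k in seq_along(iz)) {
        near <- which(abs(zc_px - zc_px[k]) < 6 & abs(xc_px - xc_px[k]) < 6)
        near <- setdiff(near, k)
        if (length(near) == 0) next
        stencil <- rbind(c(iz[k] - 1L, ix[k]), c(iz[k], ix[k]),
                         c(iz[k] + 1L, ix[k]),
                         c(iz[k], ix[k] - 1L), c(iz[k], ix[k] + 1L))
        vals <- fr[stencil]
        for (j in near) {
          pk <- fr[iz[j], ix[j]]
          d2p <- (stencil[, 1] - zc_px[j])^2 + (stencil[, 2] - xc_px[j])^2
          d2c <- (iz[j] - zc_px[j])^2 + (ix[j] - xc_px[j])^2
          vals <- vals - pk * exp(-(d2p - d2c) / (2 * sz[j]^2))
        }
        mags <- Mod(vals)
        rz <- log_parabola_offset(mags[1], mags[2], mags[3], curvature = TRUE)
        rx <- log_parabola_offset(mags[4], mags[2], mags[5], curvature = TRUE)
        zs[k] <- (iz[k] - 0.5 + rz[1]) * pixel_dz
        xs[k] <- (ix[k] - 0.5 + rx[1]) * pixel_dx
        zc_px[k] <- zs[k] / pixel_dz + 0.5
        xc_px[k] <- xs[k] / pixel_dx + 0.5
        sz[k] <- sqrt(max(mean(c(rz[2], rx[2])), 0.04))
      }
    }
  }
  tibble::tibble(z_mm = zs, x_mm = xs, intensity = img[cbind(iz, ix)])
}

# sub-pixel vertex of the parabola through log intensities at -1, 0, +1;
# exact for a Gaussian profile, falls back to a plain 3-point centroid when a
# neighbour is non-positive, and is clamped to half a pixel. With
# `curvature = TRUE` also returns the implied Gaussian variance in pixel^2
# (from the parabola curvature).
log_parabola_offset <- function(a, b, c, curvature = FALSE) {
  s2 <- 0.2025   # default psf variance guess (sigma 0.45 px) when degenerate
  if (a <= 0 || b <= 0 || c <= 0) {
    s <- a + b + c
    off <- if (s > 0) (c - a) / s else 0
  } else {
    la <- log(a); lb <- log(b); lc <- log(c)
    den <- la - 2 * lb + lc
    if (den < 0) {
      off <- 0.5 * (la - lc) / den
      s2 <- -1 / den
    } else off <- 0
  }
  off <- max(min(off, 0.5), -0.5)
  if (curvature) c(off, s2) else off
}

#' Localize microbubbles across a filtered stack
#'
#' Applies the per-block SVD clutter filter (`n_remove = 10` for the
#' localization-microscopy preset) and runs [detect_bubbles()] on every
#' filtered frame.
#'
#' @param stack A `fus_stack`.
#' @param min_intensity Detection threshold.
#' @param n_remove Singular vectors removed per block (0 to skip filtering).
#' @param neighborhood,refine Passed to [detect_bubbles()].
#' @return Tibble of localizations: `frame`, `z_mm`, `x_mm`, `intensity`.
#' @export
ulm_localize <- function(stack, min_intensity, n_remove = 10,
                         neighborhood = 3L, refine = c("gaussian", "centroid")) {
  stopifnot(inherits(stack, "fus_stack"))
  refine <- match.arg(refine)
  cfg <- stack$config
  n_t <- n_frames(stack)
  B <- cfg$block_size
  n_b <- n_t %/% B
  out <- vector("list", n_t)
  for (b in seq_len(n_b)) {
    idx <- ((b - 1) * B + 1):(b * B)
    blk <- if (n_remove > 0) {
      svd_filter_block(stack$frames[, , idx, drop = FALSE], n_remove)
    } else stack$frames[, , idx, drop = FALSE]
    for (k in seq_along(idx)) {
      loc <- detect_bubbles(blk[, , k], min_intensity, neighborhood,
                            cfg$pixel_dz, cfg$pixel_dx, refine)
      if (nrow(loc) > 0) out[[idx[k]]] <- dplyr::mutate(loc, frame = idx[k], .before = 1)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), z_mm = numeric(),
                          x_mm = numeric(), intensity = numeric())
  }
  res
}

#' Link localizations into microbubble tracks
#'
#' Classical particle tracking: between consecutive frames the detections
#' are paired by an optimal (Hungarian/Munkres) assignment that minimises
#' the total Euclidean link distance, subject to the gating constraint that
#' no link exceeds `max_link_mm`; leaving a detection unlinked costs
#' `max_link_mm`, so the optimum links as many pairs as the gate allows.
#' Unmatched detections start new tracks; a bubble missing from a frame
#' terminates its track unless `max_gap > 0` allows linking across up to
#' that many skipped frames (with the gate scaled by the gap length).
#' Tracks shorter than `min_length` points are discarded.
#'
#' Determinism: detections are processed in frame order and, within a frame,
#' in their input order, so identical input yields identical track ids.
#'
#' @param localizations Tibble from [ulm_localize()] (`frame`, `z_mm`,
#'   `x_mm`, optional `intensity`).
#' @param max_link_mm Gating distance in mm.
#' @param min_length Minimum number of points per retained track.
#' @param max_gap Frames a bubble may be missed without ending its track.
#' @return A `fus_tracks` tibble: `track_id`, `frame`, `z_mm`, `x_mm`.
#' @export
link_tracks <- function(localizations, max_link_mm, min_length = 4L,
                        max_gap = 0L) {
  df <- as.data.frame(localizations)
  stopifnot(all(c("frame", "z_mm", "x_mm") %in% names(df)))
  assert_scalar_num(max_link_mm, "max_link_mm", 0, strict = TRUE)
  if (nrow(df) == 0) {
    out <- tibble::tibble(track_id = integer(), frame = integer(),
                          z_mm = numeric(), x_mm = numeric())
    class(out) <- c("fus_tracks", class(out))
    return(out)
  }
  df <- df[order(df$frame), , drop = FALSE]
  frames <- sort(unique(df$frame))
  byf <- split(seq_len(nrow(df)), df$frame)
  track_of <- integer(nrow(df))
  next_id <- 1L
  # open tracks: last point index, last frame
  open_idx <- integer(0)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- byf[[as.character(f)]]
    # close tracks whose last frame is too old
    if (length(open_idx)) {
      last_f <- df$frame[open_idx]
      open_idx <- open_idx[f - last_f <= max_gap + 1L]
    }
    n_open <- length(open_idx); n_cur <- length(cur)
    if (n_open > 0 && n_cur > 0) {
      gap <- f - df$frame[open_idx]                  # >= 1
      D <- sqrt(outer(df$z_mm[open_idx], df$z_mm[cur], "-")^2 +
                outer(df$x_mm[open_idx], df$x_mm[cur], "-")^2)
      gate <- max_link_mm * gap                      # per-row gate
      D[D > gate] <- Inf
      # pad to square: alternative (non-link) cost = max_link_mm
      n <- n_open + n_cur
      C <- matrix(Inf, n, n)
      C[seq_len(n_open), seq_len(n_cur)] <- D
      for (i in seq_len(n_open)) C[i, n_cur + i] <- max_link_mm
      for (j in seq_len(n_cur)) C[n_open + j, j] <- max_link_mm
      C[(n_open + 1):n, (n_cur + 1):n] <- 0
      perm <- solve_assignment(C)
      for (i in seq_len(n_open)) {
        j <- perm[i]
        if (j <= n_cur && is.finite(D[i, j])) {
          track_of[cur[j]] <- track_of[open_idx[i]]
          open_idx[i] <- cur[j]
        }
      }
    }
    new_pts <- cur[track_of[cur] == 0L]
    if (length(new_pts)) {
      track_of[new_pts] <- next_id + seq_along(new_pts) - 1L
      next_id <- next_id + length(new_pts)
      open_idx <- c(open_idx, new_pts)
    }
    # keep open list ordered by track id for stable assignment order
    open_idx <- open_idx[order(track_of[open_idx])]
  }
  df$track_id <- track_of
  counts <- table(df$track_id)
  keep <- df$track_id %in% as.integer(names(counts)[counts >= min_length])
  df <- df[keep, , drop = FALSE]
  # renumber retained tracks consecutively, in order of first appearance
  df$track_id <- match(df$track_id, unique(df$track_id))
  out <- tibble::as_tibble(df[c("track_id", "frame", "z_mm", "x_mm")])
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  class(out) <- c("fus_tracks", class(out))
  out
}

#' Compute per-segment track velocities
#'
#' For every pair of successive points in a track the velocity is
#' `(delta position) * framerate / (delta frame)`, with components signed in
#' the grid convention (`z` positive downward). The segment velocity is
#' stored on the segment's starting point; the last point of each track has
#' `NA` velocities.
#'
#' @param tracks A `fus_tracks` tibble (every track needs >= 2 points).
#' @param framerate Frames per second.
#' @return The tracks tibble with added columns `vz`, `vx` (mm/s) and
#'   `speed` (`sqrt(vz^2 + vx^2)`).
#' @export
track_velocities <- function(tracks, framerate) {
  assert_scalar_num(framerate, "framerate", 0, strict = TRUE)
  if (any(table(tracks$track_id) < 2)) {
    stop("every track needs at least 2 points to carry a velocity", call. = FALSE)
  }
  out <- dplyr::group_by(tracks, .data$track_id)
  out <- dplyr::mutate(
    out,
    vz = (dplyr::lead(.data$z_mm) - .data$z_mm) * framerate /
      (dplyr::lead(.data$frame) - .data$frame),
    vx = (dplyr::lead(.data$x_mm) - .data$x_mm) * framerate /
      (dplyr::lead(.data$frame) - .data$frame),
    speed = sqrt(.data$vz^2 + .data$vx^2))
  out <- dplyr::ungroup(out)
  class(out) <- c("fus_tracks", class(tibble::tibble()))
  out
}

#' Per-track summaries
#' @param x A `fus_tracks` tibble with velocities.
#' @param ... Unused.
#' @return Tibble with one row per track: `track_id`, `n_points`,
#'   `mean_speed` (mm/s).
#' @method tidy fus_tracks
#' @export
tidy.fus_tracks <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$track_id),
                   n_points = dplyr::n(),
                   mean_speed = mean(.data$speed, na.rm = TRUE),
                   .groups = "drop")
}

#' Render super-resolved ULM maps
#'
#' Accumulates localizations and segment velocities on a super-resolved
#' grid (default pitch ~6.5 um): the **density** map counts all retained
#' localizations per pixel; the **speed** map is the mean segment velocity
#' magnitude over segments starting in the pixel; the signed **vz** map
#' (mean axial velocity) separates up- from down-flows; and a coarser
#' **vector field** holds the mean `(vz, vx)` per cell.
#'
#' @param tracks A `fus_tracks` tibble with velocities (from
#'   [track_velocities()]).
#' @param config The acquisition `fus_config` (for the field-of-view
#'   extent).
#' @param pitch_um Super-resolved pixel pitch in micrometres.
#' @param vector_pitch_um Vector-field cell pitch in micrometres.
#' @return A `fus_ulm_maps`: matrices `density`, `speed`, `vz`, a tibble
#'   `vectors` (`z_mm`, `x_mm`, `vz`, `vx`, `n`), and `pitch_um`.
#' @export
render_maps <- function(tracks, config, pitch_um = 6.5, vector_pitch_um = 100) {
  assert_scalar_num(pitch_um, "pitch_um", 0, strict = TRUE)
  assert_scalar_num(vector_pitch_um, "vector_pitch_um", 0, strict = TRUE)
  pitch <- pitch_um / 1000
  nz <- as.integer(ceiling(config$depth_mm / pitch - 1e-9))
  nx <- as.integer(ceiling(config$width_mm / pitch - 1e-9))
  density <- matrix(0L, nz, nx)
  speed <- matrix(NA_real_, nz, nx)
  vzmap <- matrix(NA_real_, nz, nx)
  vectors <- tibble::tibble(z_mm = numeric(), x_mm = numeric(),
                            vz = numeric(), vx = numeric(), n = integer())
  if (nrow(tracks) > 0) {
    iz <- pmin(pmax(floor(tracks$z_mm / pitch) + 1L, 1L), nz)
    ix <- pmin(pmax(floor(tracks$x_mm / pitch) + 1L, 1L), nx)
    for (k in seq_len(nrow(tracks))) {
      density[iz[k], ix[k]] <- density[iz[k], ix[k]] + 1L
    }
    seg <- !is.na(tracks$speed)
    if (any(seg)) {
      key <- paste(iz[seg], ix[seg])
      sp <- tapply(tracks$speed[seg], key, mean)
      vzm <- tapply(tracks$vz[seg], key, mean)
      ij <- do.call(rbind, lapply(strsplit(names(sp), " "), as.integer))
      speed[ij] <- sp
      vzmap[ij] <- vzm
      # coarse vector field
      vp <- vector_pitch_um / 1000
      czi <- floor(tracks$z_mm[seg] / vp)
      cxi <- floor(tracks$x_mm[seg] / vp)
      ckey <- paste(czi, cxi)
      vectors <- tibble::tibble(
        z_mm = tapply(tracks$z_mm[seg], ckey, mean)[unique(ckey)],
        x_mm = tapply(tracks$x_mm[seg], ckey, mean)[unique(ckey)],
        vz = tapply(tracks$vz[seg], ckey, mean)[unique(ckey)],
        vx = tapply(tracks$vx[seg], ckey, mean)[unique(ckey)],
        n = as.integer(table(ckey)[unique(ckey)]))
    }
  }
  structure(
    list(density = density, speed = speed, vz = vzmap, vectors = vectors,
         pitch_um = pitch_um, vector_pitch_um = vector_pitch_um,
         config = config),
    class = "fus_ulm_maps")
}

#' @export
print.fus_ulm_maps <- function(x, ...) {
  cat(sprintf("<fus_ulm_maps> %d x %d px at %.2f um, %d localizations\n",
              nrow(x$density), ncol(x$density), x$pitch_um, sum(x$density)))
  invisible(x)
}
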