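# On-disk formats. Frame stacks and Power Doppler series are stored as
# multi-frame 32-bit float TIFF plus a JSON sidecar (`<path>.json`) carrying
# the acquisition metadata; complex IQ stacks interleave real and imaginary
# pages (2 * n_t pages) so the round trip preserves phase. Tracks and dBV
# traces travel as plain CSV (comma separator, '.' decimal, header row).

required_meta <- c("framerate", "block_size", "n_blocks",
                   "pixel_dz", "pixel_dx", "depth_mm", "width_mm")

sidecar_path <- function(path) paste0(path, ".json")

config_to_meta <- function(config, extra = list()) {
  c(config[c(required_meta, "prf", "angles")], extra)
}

meta_to_config <- function(meta) {
  # JSON has no scalar NULL: absent/empty fields come back as empty lists
  blank <- vapply(meta, function(x) is.null(x) || length(x) == 0, logical(1))
  meta[blank] <- list(NULL)
  missing <- setdiff(required_meta, names(meta)[!blank])
  if (length(missing)) {
    stop(sprintf("metadata sidecar is missing attribute(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  acquisition_config(
    framerate = meta$framerate, block_size = meta$block_size,
    n_blocks = meta$n_blocks, prf = meta$prf, angles = meta$angles,
    pixel_dz = meta$pixel_dz, pixel_dx = meta$pixel_dx,
    depth_mm = meta$depth_mm, width_mm = meta$width_mm)
}

# scale a set of matrices to [0, 1] for TIFF storage, recording the range
norm_pages <- function(pages) {
  rng <- range(unlist(lapply(pages, range)))
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  list(pages = lapply(pages, function(m) (m - rng[1]) / (rng[2] - rng[1])),
       rng = rng)
}

#' Write / read a frame stack
#'
#' `write_stack()` stores the frames as a multi-frame 32-bit float TIFF with
#' a JSON metadata sidecar (`<path>.json`); complex stacks interleave real
#' and imaginary pages so phase is preserved. `read_stack()` reverses the
#' operation and validates the metadata. Values round-trip to 32-bit float
#' precision.
#'
#' @param stack A `fus_stack`.
#' @param path Output TIFF path.
#' @return `write_stack()` the path, invisibly; `read_stack()` a
#'   `fus_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fus_stack"))
  d <- dim(stack$frames)
  cplx <- is.complex(stack$frames)
  pages <- vector("list", if (cplx) 2 * d[3] else d[3])
  for (k in seq_len(d[3])) {
    if (cplx) {
      pages[[2 * k - 1]] <- Re(stack$frames[, , k])
      pages[[2 * k]] <- Im(stack$frames[, , k])
    } else {
      pages[[k]] <- stack$frames[, , k]
    }
  }
  np <- norm_pages(pages)
  tiff::writeTIFF(np$pages, path, bits.per.sample = 32L)
  meta <- config_to_meta(stack$config,
                         list(t0 = stack$t0, complex = cplx, n_t = d[3],
                              value_range = np$rng))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(sidecar_path(path))) {
    stop(sprintf("metadata sidecar not found: %s", sidecar_path(path)), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  config <- meta_to_config(meta)
  pages <- tiff::readTIFF(path, all = TRUE)
  rng <- meta$value_range
  pages <- lapply(pages, function(m) m * (rng[2] - rng[1]) + rng[1])
  n_t <- meta$n_t
  if (isTRUE(meta$complex)) {
    frames <- array(0i, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), n_t))
    for (k in seq_len(n_t)) {
      frames[, , k] <- complex(real = pages[[2 * k - 1]],
                               imaginary = pages[[2 * k]])
    }
  } else {
    frames <- array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]), n_t))
  }
  frame_stack(frames, config, t0 = meta$t0 %||% 0)
}

#' Write / read a Power Doppler series
#'
#' Same container as [write_stack()]: one 32-bit TIFF page per Power Doppler
#' image plus a JSON sidecar with the frame interval and acquisition
#' metadata.
#'
#' @param pd A `fus_pd`.
#' @param path Output TIFF path.
#' @return `write_pd()` the path, invisibly; `read_pd()` a `fus_pd`.
#' @export
write_pd <- function(pd, path) {
  stopifnot(inherits(pd, "fus_pd"))
  d <- dim(pd$images)
  pages <- lapply(seq_len(d[3]), function(k) pd$images[, , k])
  np <- norm_pages(pages)
  tiff::writeTIFF(np$pages, path, bits.per.sample = 32L)
  meta <- config_to_meta(pd$config,
                         list(frame_interval = pd$frame_interval,
                              n_removed = pd$n_removed, n_images = d[3],
                              value_range = np$rng))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pd
#' @export
read_pd <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  config <- meta_to_config(meta)
  pages <- tiff::readTIFF(path, all = TRUE)
  rng <- meta$value_range
  imgs <- array(unlist(lapply(pages, function(m) m * (rng[2] - rng[1]) + rng[1])),
                dim = c(nrow(pages[[1]]), ncol(pages[[1]]), meta$n_images))
  imgs[imgs < 0] <- 0   # clip float round-off below zero
  pd_series(imgs, meta$frame_interval, config, meta$n_removed)
}

#' Write / read microbubble tracks as CSV
#'
#' Columns: `track_id`, `frame`, `z_mm`, `x_mm` and, when present, `vz`,
#' `vx`, `speed` (mm/s).
#'
#' @param tracks A `fus_tracks` tibble.
#' @param path CSV path.
#' @return `write_tracks()` the path, invisibly; `read_tracks()` a
#'   `fus_tracks` tibble.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tibble::as_tibble(tracks), path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("fus_tracks", class(out))
  out
}

#' Write a dBV trace as CSV
#' @param dbv A `fus_dbv`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_dbv <- function(dbv, path) {
  readr::write_csv(tibble::as_tibble(dbv), path)
  invisible(path)
}
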