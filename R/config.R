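#' Acquisition configuration
#'
#' Describes one ultrafast acquisition: compound framerate, block structure,
#' pulse repetition frequency (PRF), plane-wave angles and the imaging grid.
#' All geometry is in millimetres with `z` the depth axis (positive downward)
#' and `x` the lateral axis; frames are stored as `(n_z, n_x, n_t)` arrays.
#'
#' When both `prf` and `angles` are supplied the compounding constraint
#' `framerate <= prf / length(angles)` is enforced: a compound frame needs one
#' emission per angle, so the compound framerate cannot exceed
#' `prf / n_angles` (systems may idle between blocks, so strict equality is
#' not required).
#'
#' @param framerate Compound framerate in frames/second.
#' @param block_size Frames per processing block (integer, >= 2).
#' @param n_blocks Number of blocks in the acquisition.
#' @param prf Pulse repetition frequency in Hz, or `NULL`.
#' @param angles Plane-wave tilt angles in degrees, or `NULL`.
#' @param pixel_dz,pixel_dx Grid spacing in mm (axial, lateral).
#' @param depth_mm Imaging depth in mm.
#' @param width_mm Lateral field of view in mm.
#' @return An object of class `fus_config` (a validated list) with derived
#'   grid dimensions `n_z`, `n_x`.
#' @examples
#' cfg <- acquisition_config(framerate = 500, block_size = 200, n_blocks = 5)
#' cfg$n_z
#' @export
acquisition_config <- function(framerate, block_size, n_blocks = 1L,
                               prf = NULL, angles = NULL,
                               pixel_dz = 0.1, pixel_dx = 0.1,
                               depth_mm = 12, width_mm = 12.8) {
  assert_scalar_num(framerate, "framerate", 0, strict = TRUE)
  assert_scalar_num(block_size, "block_size", 2)
  if (!is_wholenumber(block_size)) stop("`block_size` must be an integer", call. = FALSE)
  assert_scalar_num(n_blocks, "n_blocks", 1)
  assert_scalar_num(pixel_dz, "pixel_dz", 0, strict = TRUE)
  assert_scalar_num(pixel_dx, "pixel_dx", 0, strict = TRUE)
  assert_scalar_num(depth_mm, "depth_mm", 0, strict = TRUE)
  assert_scalar_num(width_mm, "width_mm", 0, strict = TRUE)
  if (!is.null(prf)) assert_scalar_num(prf, "prf", 0, strict = TRUE)
  if (!is.null(prf) && !is.null(angles) && length(angles) > 0) {
    max_fr <- prf / length(angles)
    if (framerate > max_fr * (1 + 1e-9)) {
      stop(sprintf(
        "framerate (%g Hz) exceeds prf / n_angles = %g Hz: compounding impossible",
        framerate, max_fr), call. = FALSE)
    }
  }
  structure(
    list(
      framerate = framerate,
      block_size = as.integer(block_size),
      n_blocks = as.integer(n_blocks),
      prf = prf,
      angles = angles,
      pixel_dz = pixel_dz,
      pixel_dx = pixel_dx,
      depth_mm = depth_mm,
      width_mm = width_mm,
      n_z = as.integer(round(depth_mm / pixel_dz)),
      n_x = as.integer(round(width_mm / pixel_dx))
    ),
    class = "fus_config"
  )
}

#' @export
print.fus_config <- function(x, ...) {
  cat(sprintf(
    "<fus_config> %d x %d px (%.0f um x %.0f um), %g Hz, %d frames/block x %d blocks\n",
    x$n_z, x$n_x, x$pixel_dz * 1000, x$pixel_dx * 1000,
    x$framerate, x$block_size, x$n_blocks))
  if (!is.null(x$prf)) cat(sprintf("  PRF %g Hz, %d angles\n", x$prf, length(x$angles)))
  invisible(x)
}

#' Preset configurations for the two acquisition types
#'
#' `config_fus()` is the functional-ultrasound sequence: ten tilted plane
#' waves (-10 to 10 degrees) at 5.5 kHz PRF, beamformed into blocks of 200
#' compound frames at 500 Hz, i.e. one Power Doppler image every 400 ms.
#' `config_ulm()` is the localization-microscopy sequence: five angles
#' (-5, -2, 0, 2, 5 degrees) at 5 kHz PRF, blocks of 400 compound frames at
#' 1000 Hz, 750 blocks (300 s) by default, 12 mm imaging depth.
#'
#' @param n_blocks Number of blocks.
#' @param ... Passed on to [acquisition_config()] (e.g. smaller grids for
#'   simulation studies).
#' @return A `fus_config`.
#' @export
config_fus <- function(n_blocks = 1L, ...) {
  args <- utils::modifyList(
    list(framerate = 500, block_size = 200L, n_blocks = n_blocks,
         prf = 5500, angles = seq(-10, 10, length.out = 10)),
    list(...))
  do.call(acquisition_config, args)
}

#' @rdname config_fus
#' @export
config_ulm <- function(n_blocks = 750L, ...) {
  args <- utils::modifyList(
    list(framerate = 1000, block_size = 400L, n_blocks = n_blocks,
         prf = 5000, angles = c(-5, -2, 0, 2, 5), depth_mm = 12),
    list(...))
  do.call(acquisition_config, args)
}

#' Construct a frame stack
#'
#' A frame stack holds beamformed, angle-compounded ultrafast frames as a
#' `(n_z, n_x, n_t)` array (complex IQ data by default; real mode supported)
#' together with its acquisition configuration.
#'
#' @param frames 3-D numeric or complex array `(n_z, n_x, n_t)`.
#' @param config A `fus_config` whose grid matches `frames`.
#' @param t0 Acquisition start time in seconds.
#' @return An object of class `fus_stack`.
#' @export
frame_stack <- function(frames, config, t0 = 0) {
  if (length(dim(frames)) != 3L) stop("`frames` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(Re(frames))) || !all(is.finite(Im(frames)))) {
    stop("`frames` contains non-finite values", call. = FALSE)
  }
  d <- dim(frames)
  if (d[1] != config$n_z || d[2] != config$n_x) {
    stop(sprintf("frame grid %dx%d does not match config grid %dx%d",
                 d[1], d[2], config$n_z, config$n_x), call. = FALSE)
  }
  structure(list(frames = frames, config = config, t0 = t0), class = "fus_stack")
}

#' @export
print.fus_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fus_stack> %d x %d x %d frames (%s), %g Hz\n",
              d[1], d[2], d[3],
              if (is.complex(x$frames)) "complex" else "real",
              x$config$framerate))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `fus_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]
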