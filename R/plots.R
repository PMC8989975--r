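# ggplot2 autoplot methods for the main result types

#' Plot a Power Doppler series
#'
#' Shows the temporal mean Power Doppler image (log scale by default), the
#' ultrafast-Doppler vascular map.
#'
#' @param object A `fus_pd`.
#' @param log Use a log10 colour scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fus_pd
#' @export
autoplot.fus_pd <- function(object, log = TRUE, ...) {
  d <- dim(object$images)
  img <- apply(object$images, c(1, 2), mean)
  df <- tibble::tibble(
    z_mm = rep(pixel_centers(d[1], object$config$pixel_dz), times = d[2]),
    x_mm = rep(pixel_centers(d[2], object$config$pixel_dx), each = d[1]),
    pd = as.vector(img))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm,
                                        fill = if (log) log10(.data$pd + 1e-12) else .data$pd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (log) "log10 PD" else "PD") +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", title = "Mean Power Doppler")
  p
}

#' Plot an activation map
#'
#' Z-scores of the Bonferroni-significant pixels over the imaging frame.
#'
#' @param object A `fus_activation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fus_activation
#' @export
autoplot.fus_activation <- function(object, ...) {
  df <- tidy(object)
  df$zscore[!df$significant] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm, fill = .data$zscore)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "Z", option = "inferno", na.value = "grey15") +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = "Activation map (Bonferroni-significant Z)")
}

#' Plot a percent blood-volume trace
#'
#' dBV over time with the stimulation frames shaded.
#'
#' @param object A `fus_dbv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fus_dbv
#' @export
autoplot.fus_dbv <- function(object, ...) {
  df <- tibble::as_tibble(object)
  shade <- df[df$stim, , drop = FALSE]
  dtf <- if (nrow(df) > 1) diff(df$t[1:2]) else 1
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$dbv))
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$t - dtf / 2, xmax = .data$t + dtf / 2,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "BV (%)"),
                  title = "Relative blood volume in ROI")
}

#' Plot super-resolved ULM maps
#'
#' Density (log counts) or mean-speed map on the super-resolved grid.
#'
#' @param object A `fus_ulm_maps`.
#' @param which `"density"`, `"speed"` or `"vz"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fus_ulm_maps
#' @export
autoplot.fus_ulm_maps <- function(object, which = c("density", "speed", "vz"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  pitch <- object$pitch_um / 1000
  df <- tibble::tibble(
    z_mm = rep((seq_len(nrow(m)) - 0.5) * pitch, times = ncol(m)),
    x_mm = rep((seq_len(ncol(m)) - 0.5) * pitch, each = nrow(m)),
    value = as.vector(m))
  if (which == "density") {
    df$value <- log10(df$value + 1)
    lab <- "log10(count + 1)"
  } else lab <- paste(which, "(mm/s)")
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = sprintf("ULM %s map (%.1f um pixels)", which, object$pitch_um))
}

#' @importFrom rlang .data
NULL
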