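#' Pixelwise GLM activation mapping of a Power Doppler series
#'
#' Fits the design (stimulus regressor + intercept) to every pixel's Power
#' Doppler time course by ordinary least squares, forms `t = beta / SE`,
#' converts it to a one-sided p-value from the t distribution on the
#' residual degrees of freedom (activation is a blood-volume increase;
#' `two_sided = TRUE` switches to a two-sided test), maps it to a Z-score
#' `Z = qnorm(1 - p)`, and marks pixels significant under Bonferroni control
#' of the family-wise level `alpha` over all pixels in the frame.
#'
#' Pixels with (numerically) zero residual variance would give infinite
#' Z-scores; their Z is reported capped at `z_cap` (8.2, i.e. p ~ 1e-16) and
#' a message reports how many were capped.
#'
#' @param series A `fus_pd`.
#' @param design Design matrix from [build_design()].
#' @param alpha Family-wise significance level.
#' @param two_sided Use a two-sided test instead of the one-sided default.
#' @param correction `"bonferroni"` (default) controls the family-wise error
#'   over all pixels; `"none"` thresholds each pixel at `alpha` uncorrected
#'   (a display threshold, not an error-controlled map).
#' @param z_cap Cap for infinite Z-scores.
#' @return A `fus_activation`: matrices `z`, `p`, `beta`, logical `mask`
#'   (Bonferroni-significant pixels), `alpha`, `n_tests`, `df`, `config`.
#' @export
glm_fit <- function(series, design, alpha = 0.05, two_sided = FALSE,
                    correction = c("bonferroni", "none"), z_cap = 8.2) {
  correction <- match.arg(correction)
  stopifnot(inherits(series, "fus_pd"))
  X <- as.matrix(design)
  d <- dim(series$images)
  n <- d[3]; p <- ncol(X)
  if (nrow(X) != n) stop("design has a different number of frames than the series", call. = FALSE)
  if (n < p + 2) stop("need at least n_regressors + 2 frames", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Y <- t(matrix(series$images, d[1] * d[2], n))        # n x n_px
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)                      # p x n_px
  res <- Y - X %*% B
  df <- n - p
  s2 <- colSums(res^2) / df
  j <- which(colnames(X) == "stim")
  if (length(j) != 1) j <- p                           # last column by convention
  se <- sqrt(pmax(s2 * XtXinv[j, j], 0))
  tval <- ifelse(se > 0, B[j, ] / se, Inf * sign(B[j, ]))
  if (two_sided) {
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  } else {
    pval <- stats::pt(tval, df, lower.tail = FALSE)
  }
  z <- stats::qnorm(pval, lower.tail = FALSE)
  n_capped <- sum(!is.finite(z) & pval < 0.5)
  z <- pmin(z, z_cap)
  z[!is.finite(z) & pval >= 0.5] <- -z_cap
  if (n_capped > 0) {
    rlang::inform(sprintf("%d pixel(s) with ~zero residual variance: Z capped at %g",
                          n_capped, z_cap))
  }
  n_tests <- if (correction == "bonferroni") d[1] * d[2] else 1L
  structure(
    list(z = matrix(z, d[1], d[2]), p = matrix(pval, d[1], d[2]),
         beta = matrix(B[j, ], d[1], d[2]),
         mask = matrix(pval < alpha / n_tests, d[1], d[2]),
         alpha = alpha, n_tests = n_tests, df = df,
         config = series$config),
    class = "fus_activation")
}

#' @export
print.fus_activation <- function(x, ...) {
  cat(sprintf("<fus_activation> %d x %d px, %d significant (Bonferroni, alpha = %g), max Z = %.2f\n",
              nrow(x$z), ncol(x$z), sum(x$mask), x$alpha, max(x$z)))
  invisible(x)
}

#' @method tidy fus_activation
#' @export
tidy.fus_activation <- function(x, ...) {
  d <- dim(x$z)
  zc <- pixel_centers(d[1], x$config$pixel_dz)
  xc <- pixel_centers(d[2], x$config$pixel_dx)
  tibble::tibble(
    z_mm = rep(zc, times = d[2]), x_mm = rep(xc, each = d[1]),
    zscore = as.vector(x$z), p = as.vector(x$p), beta = as.vector(x$beta),
    significant = as.vector(x$mask))
}

#' @method glance fus_activation
#' @export
glance.fus_activation <- function(x, ...) {
  tibble::tibble(n_significant = sum(x$mask), max_z = max(x$z),
                 alpha = x$alpha, n_tests = x$n_tests, df = x$df)
}

# 8-connected component labelling by flood fill
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1, 2)
    lab[i0, j0] <- cur
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Extract the activated region of interest
#'
#' Returns the 8-connected component of the Bonferroni-significant mask that
#' contains the maximal Z-score (ties broken by first position in
#' column-major raster order). This is the ipsilateral ROI drawn around the
#' activation focus on the thresholded Z map.
#'
#' @param map A `fus_activation` with at least one significant pixel.
#' @return A `fus_roi`: logical pixel `mask`, `side`, and `provenance`
#'   (threshold used, mirror axis when mirrored).
#' @export
extract_roi <- function(map) {
  stopifnot(inherits(map, "fus_activation"))
  if (!any(map$mask)) stop("no activation: the significance mask is empty", call. = FALSE)
  lab <- label_components(map$mask)
  zm <- map$z
  zm[!map$mask] <- -Inf
  peak <- which.max(zm)            # first max in column-major order
  roi_mask <- lab == lab[peak]
  structure(
    list(mask = roi_mask, side = "ipsilateral",
         provenance = list(alpha = map$alpha, n_tests = map$n_tests,
                           threshold = map$alpha / map$n_tests,
                           midline_x = NULL),
         config = map$config),
    class = "fus_roi")
}

#' Mirror an ROI about a vertical midline
#'
#' Reflects the pixel mask about the line `x = midline_x` (mm) to obtain the
#' symmetric contralateral ROI. The reflection preserves the pixel count;
#' an ROI whose reflection falls outside the grid is an error.
#'
#' @param roi A `fus_roi`.
#' @param midline_x Mirror axis position (mm), inside the grid.
#' @return The mirrored `fus_roi` (side label flipped).
#' @export
mirror_roi <- function(roi, midline_x) {
  stopifnot(inherits(roi, "fus_roi"))
  cfg <- roi$config
  width <- ncol(roi$mask) * cfg$pixel_dx
  if (midline_x < 0 || midline_x > width) {
    stop("`midline_x` must lie inside the imaging grid", call. = FALSE)
  }
  idx <- which(roi$mask, arr.ind = TRUE)
  # pixel centre x_j = (j - 1/2) dx reflects to 2 m - x, i.e. column
  # j' = 2 m / dx + 1 - j
  jj <- round(2 * midline_x / cfg$pixel_dx + 1 - idx[, 2])
  if (any(jj < 1 | jj > ncol(roi$mask))) {
    stop("mirrored ROI falls outside the imaging grid", call. = FALSE)
  }
  m <- matrix(FALSE, nrow(roi$mask), ncol(roi$mask))
  m[cbind(idx[, 1], jj)] <- TRUE
  structure(
    list(mask = m,
         side = if (identical(roi$side, "ipsilateral")) "contralateral" else "ipsilateral",
         provenance = utils::modifyList(roi$provenance, list(midline_x = midline_x)),
         config = cfg),
    class = "fus_roi")
}

#' @export
print.fus_roi <- function(x, ...) {
  cat(sprintf("<fus_roi> %s, %d px\n", x$side, sum(x$mask)))
  invisible(x)
}

#' Percent blood-volume change within an ROI
#'
#' Averages the Power Doppler series over the ROI pixels to a single time
#' course `s(t)`, computes the baseline `b` as the mean of `s(t)` over the
#' frames where the stimulation indicator is strictly zero, and expresses
#' the signal as a relative difference in percent,
#' `dbv(t) = 100 * (s(t) - b) / b`. Summary values `dbv_bl` and `dbv_stim`
#' are the means of `dbv` over the baseline and stimulation frames
#' (`dbv_bl` is exactly 0 by construction).
#'
#' @param series A `fus_pd`.
#' @param roi A `fus_roi`.
#' @param paradigm The `fus_paradigm`; at least one frame must be entirely
#'   stimulus-free.
#' @return A `fus_dbv`: tibble with columns `t`, `dbv`, `stim`, and
#'   attributes `baseline_value`, `dbv_bl`, `dbv_stim`.
#' @export
delta_bv <- function(series, roi, paradigm) {
  stopifnot(inherits(series, "fus_pd"), inherits(roi, "fus_roi"),
            inherits(paradigm, "fus_paradigm"))
  d <- dim(series$images)
  if (!all(dim(roi$mask) == d[1:2])) {
    stop("ROI grid does not match the Power Doppler grid", call. = FALSE)
  }
  if (!any(roi$mask)) stop("ROI is empty", call. = FALSE)
  flat <- matrix(series$images, d[1] * d[2], d[3])
  s <- colMeans(flat[as.vector(roi$mask), , drop = FALSE])
  stim <- classify_frames(paradigm, d[3], series$frame_interval)
  if (!any(!stim)) stop("paradigm leaves no stimulus-free frame for the baseline", call. = FALSE)
  b <- mean(s[!stim])
  if (b <= 0) stop("non-physical Power Doppler: baseline <= 0", call. = FALSE)
  dbv <- 100 * (s - b) / b
  out <- tibble::tibble(t = (seq_len(d[3]) - 0.5) * series$frame_interval,
                        dbv = dbv, stim = stim)
  structure(out,
            class = c("fus_dbv", class(out)),
            baseline_value = b,
            dbv_bl = mean(dbv[!stim]),
            dbv_stim = if (any(stim)) mean(dbv[stim]) else NA_real_)
}

#' Summaries of a percent blood-volume trace
#' @param x A `fus_dbv`.
#' @param ... Unused.
#' @return One-row tibble with `baseline_value`, `dbv_bl`, `dbv_stim`.
#' @method glance fus_dbv
#' @export
glance.fus_dbv <- function(x, ...) {
  tibble::tibble(baseline_value = attr(x, "baseline_value"),
                 dbv_bl = attr(x, "dbv_bl"),
                 dbv_stim = attr(x, "dbv_stim"))
}
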