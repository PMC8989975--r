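#' Casorati matrix of a frame block
#'
#' Reshapes a `(n_z, n_x, n_t)` block into the space-time Casorati matrix of
#' shape `(n_z * n_x) x n_t` (column-major, so the reshape is exactly
#' invertible), the object on which the SVD clutter filter operates.
#'
#' @param block 3-D array.
#' @return Matrix of shape `(n_z * n_x) x n_t` with the grid shape attached
#'   as `attr(, "grid")`.
#' @export
casorati <- function(block) {
  d <- dim(block)
  if (length(d) != 3L) stop("`block` must be a 3-D array", call. = FALSE)
  m <- block
  dim(m) <- c(d[1] * d[2], d[3])
  attr(m, "grid") <- d[1:2]
  m
}

# inverse of casorati()
uncasorati <- function(m, grid) {
  x <- m
  attributes(x) <- NULL
  dim(x) <- c(grid[1], grid[2], ncol(m))
  x
}

#' SVD clutter filter on one frame block
#'
#' Removes the `n_remove` largest singular components of the block's
#' Casorati matrix (singular values ordered descending; the "first" singular
#' vectors are the largest, which carry the quasi-static tissue signal) and
#' reconstructs the block from the remainder. For complex IQ data the
#' reconstruction uses the conjugate transpose; real data degrade gracefully
#' to the ordinary transpose.
#'
#' The projection is computed from the eigendecomposition of the temporal
#' covariance `C^H C` (`n_t x n_t`), which is algebraically identical to
#' truncating the SVD but avoids forming the `n_space x n_space` side when
#' `n_space >> n_t`.
#'
#' The filter is the orthogonal projection onto the complement of the
#' estimated clutter subspace: projecting with a *fixed* basis is idempotent
#' (`attr(, "basis")` carries the estimated temporal basis and can be passed
#' back via `basis` to re-apply the identical projector). Re-estimating the
#' subspace on already-filtered data removes the next-largest components
#' instead — an intrinsic property of truncation filters.
#'
#' @param block 3-D array `(n_z, n_x, n_t)` or a `fus_stack` whose whole
#'   extent is one block.
#' @param n_remove Number of leading singular vectors to remove,
#'   `0 <= n_remove < n_t`.
#' @param basis Optional fixed temporal basis (`n_t x k` matrix, e.g. from a
#'   previous call) to project out instead of estimating one.
#' @return The filtered block (same shape and type as the input), with the
#'   removed singular values in `attr(, "removed_sv")` and the removed
#'   temporal basis in `attr(, "basis")`.
#' @examples
#' b <- array(rnorm(8 * 8 * 20), dim = c(8, 8, 20))
#' f <- svd_filter_block(b, n_remove = 2)
#' length(attr(f, "removed_sv"))  # 2
#' @export
svd_filter_block <- function(block, n_remove, basis = NULL) {
  if (inherits(block, "fus_stack")) block <- block$frames
  d <- dim(block)
  if (length(d) != 3L) stop("`block` must be a 3-D array", call. = FALSE)
  n_t <- d[3]
  assert_scalar_num(n_remove, "n_remove", 0)
  if (n_remove >= n_t) {
    stop(sprintf("n_remove (%d) must be < n_t (%d)", n_remove, n_t), call. = FALSE)
  }
  if (!all(is.finite(Re(block))) || !all(is.finite(Im(block)))) {
    stop("block contains non-finite values", call. = FALSE)
  }
  C <- casorati(block)
  if (n_remove == 0) {
    out <- block
    attr(out, "removed_sv") <- numeric(0)
    return(out)
  }
  if (is.null(basis)) {
    G <- crossprod(Conj(C), C)          # Hermitian n_t x n_t
    e <- eigen(G, symmetric = TRUE)     # eigenvalues descending = sigma^2
    V <- e$vectors[, seq_len(n_remove), drop = FALSE]  # right singular vectors
    sv <- sqrt(pmax(e$values[seq_len(n_remove)], 0))
  } else {
    V <- as.matrix(basis)
    if (nrow(V) != n_t) stop("`basis` must have n_t rows", call. = FALSE)
    sv <- sqrt(Re(colSums(Mod(C %*% V)^2)))
  }
  CV <- C %*% V
  Cf <- C - CV %*% Conj(t(V))
  if (!is.complex(block)) Cf <- Re(Cf)
  out <- uncasorati(Cf, d[1:2])
  attr(out, "removed_sv") <- sv
  attr(out, "basis") <- V
  out
}

#' Power Doppler image of a filtered block
#'
#' Integrates the energy of the filtered frames: the pixel value is
#' `sum_t |s(z, x, t)|^2` over the block (no normalisation by the number of
#' frames). Power Doppler is proportional to the local blood volume once the
#' tissue clutter has been removed.
#'
#' @param block 3-D array `(n_z, n_x, n_t)` (typically the output of
#'   [svd_filter_block()]).
#' @return Nonnegative matrix `(n_z, n_x)`.
#' @export
power_doppler <- function(block) {
  if (inherits(block, "fus_stack")) block <- block$frames
  d <- dim(block)
  if (length(d) != 3L || d[3] < 1) stop("`block` must be a non-empty 3-D array", call. = FALSE)
  v <- rowSums(Mod(casorati(block))^2)
  matrix(v, d[1], d[2])
}

#' SVD-filter a stack block by block and form the Power Doppler series
#'
#' Splits the stack into contiguous, non-overlapping blocks of `block_size`
#' frames, applies [svd_filter_block()] independently to each, and integrates
#' each filtered block into one Power Doppler image. With the functional
#' preset (blocks of 200 frames at 500 Hz) this yields one image every
#' 400 ms. Trailing frames that do not fill a complete block are dropped
#' with a warning.
#'
#' @param stack A `fus_stack` (or 3-D array plus `config`).
#' @param block_size Frames per block; defaults to the stack's configured
#'   block size.
#' @param n_remove Singular vectors removed per block (60 for the functional
#'   preset, 10 for the localization-microscopy preset).
#' @return A `fus_pd` object: `images` array `(n_z, n_x, n_blocks)`,
#'   `frame_interval = block_size / framerate`, the configuration, and
#'   `n_removed`.
#' @export
process_stack <- function(stack, block_size = NULL, n_remove = 60) {
  stopifnot(inherits(stack, "fus_stack"))
  block_size <- block_size %||% stack$config$block_size
  n_t <- n_frames(stack)
  if (block_size > n_t) {
    stop(sprintf("block_size (%d) exceeds the stack length (%d frames)",
                 block_size, n_t), call. = FALSE)
  }
  n_b <- n_t %/% block_size
  if (n_b * block_size < n_t) {
    warning(sprintf("dropping %d trailing frames that do not fill a block",
                    n_t - n_b * block_size), call. = FALSE)
  }
  d <- dim(stack$frames)
  images <- array(0, dim = c(d[1], d[2], n_b))
  for (b in seq_len(n_b)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    filt <- svd_filter_block(stack$frames[, , idx, drop = FALSE], n_remove)
    images[, , b] <- power_doppler(filt)
  }
  pd_series(images, frame_interval = block_size / stack$config$framerate,
            config = stack$config, n_removed = n_remove)
}

#' Construct a Power Doppler series
#'
#' @param images Nonnegative array `(n_z, n_x, n_blocks)`.
#' @param frame_interval Seconds between Power Doppler images.
#' @param config Acquisition configuration.
#' @param n_removed Singular vectors removed per block.
#' @return A `fus_pd`.
#' @export
pd_series <- function(images, frame_interval, config, n_removed = NA_integer_) {
  if (length(dim(images)) != 3L) stop("`images` must be a 3-D array", call. = FALSE)
  if (any(images < 0)) stop("Power Doppler values must be >= 0", call. = FALSE)
  assert_scalar_num(frame_interval, "frame_interval", 0, strict = TRUE)
  structure(
    list(images = images, frame_interval = frame_interval,
         config = config, n_removed = n_removed),
    class = "fus_pd")
}

#' @export
print.fus_pd <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<fus_pd> %d x %d px, %d images every %g ms (n_removed = %s)\n",
              d[1], d[2], d[3], x$frame_interval * 1000, x$n_removed))
  invisible(x)
}

#' Tidy a Power Doppler series into a long tibble
#' @param x A `fus_pd`.
#' @param ... Unused.
#' @return Tibble with columns `frame`, `t`, `z_mm`, `x_mm`, `pd`.
#' @method tidy fus_pd
#' @export
tidy.fus_pd <- function(x, ...) {
  d <- dim(x$images)
  zc <- pixel_centers(d[1], x$config$pixel_dz)
  xc <- pixel_centers(d[2], x$config$pixel_dx)
  tibble::tibble(
    frame = rep(seq_len(d[3]), each = d[1] * d[2]),
    t = (rep(seq_len(d[3]), each = d[1] * d[2]) - 0.5) * x$frame_interval,
    z_mm = rep(zc, times = d[2] * d[3]),
    x_mm = rep(rep(xc, each = d[1]), times = d[3]),
    pd = as.vector(x$images))
}
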