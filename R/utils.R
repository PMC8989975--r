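# shared internal helpers

#' @importFrom rlang %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# amplitude ratio from a decibel value (20*log10 convention, documented in
# the simulator: dB values always refer to amplitude, not power)
db_to_amp <- function(db) {
  if (is.infinite(db) && db < 0) return(0)
  10^(db / 20)
}

# deterministic per-stage seed derived from the single user seed; keeps every
# stage's RNG stream independent while staying inside 32-bit integer range
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  s <- (as.double(seed) * 1009 + offs * 7919) %% 2147483646
  as.integer(s) + 1L
}

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %s", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  }
  invisible(x)
}

# pixel-centre coordinates (mm); z positive downward, x lateral
pixel_centers <- function(n, pitch) (seq_len(n) - 0.5) * pitch

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
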