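#' Stimulation paradigm
#'
#' A block-design stimulation paradigm: a set of non-overlapping stimulation
#' windows (onset, duration) inside a total acquisition duration, plus the
#' sampling interval used to rasterise the binary indicator.
#'
#' @param onsets Stimulation start times (s), sorted.
#' @param durations Stimulation durations (s), one per onset.
#' @param total_duration Total acquisition duration (s).
#' @param dt Sampling interval (s) for the indicator.
#' @return An object of class `fus_paradigm`.
#' @seealso [paradigm_preset()], [paradigm_indicator()]
#' @export
stimulus_paradigm <- function(onsets, durations, total_duration, dt = 0.1) {
  assert_scalar_num(total_duration, "total_duration", 0, strict = TRUE)
  assert_scalar_num(dt, "dt", 0, strict = TRUE)
  if (length(onsets) != length(durations)) {
    stop("`onsets` and `durations` must have the same length", call. = FALSE)
  }
  if (length(onsets) > 0) {
    if (is.unsorted(onsets, strictly = TRUE)) {
      stop("`onsets` must be strictly increasing", call. = FALSE)
    }
    if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
    ends <- onsets + durations
    if (any(ends > total_duration + 1e-9)) {
      stop("every onset + duration must be <= total_duration", call. = FALSE)
    }
    if (length(onsets) > 1 && any(onsets[-1] < ends[-length(ends)] - 1e-9)) {
      stop("stimulation windows must not overlap", call. = FALSE)
    }
  }
  structure(
    list(onsets = as.numeric(onsets), durations = as.numeric(durations),
         total_duration = total_duration, dt = dt),
    class = "fus_paradigm")
}

#' @export
print.fus_paradigm <- function(x, ...) {
  cat(sprintf("<fus_paradigm> %d stimulation(s), total %g s (dt = %g s)\n",
              length(x$onsets), x$total_duration, x$dt))
  invisible(x)
}

#' Paradigm presets for the peripheral stimulation designs
#'
#' Encodes the four stimulation designs used for evoked trigeminal and barrel
#' cortex responses:
#'
#' * `corneal_mech`: six 10-s mechanical corneal stimulations separated by
#'   20 s, with 30 s of rest before and after (total 220 s).
#' * `von_frey`: four 5-s static mechanical stimulations separated by 55 s,
#'   with 60 s of rest before and after (total 305 s).
#' * `whisker`: six 20-s whisker-pad stimulation trains separated by 20 s
#'   (the 4-Hz deflections inside each train are below the indicator's
#'   resolution of interest and are encoded as a filled block), with 30 s of
#'   rest before and after (total 280 s).
#' * `capsaicin`: one 180-s chemical application after a 60-s baseline and
#'   followed by 60 s after washout (total 300 s). The response to capsaicin
#'   is phasic rather than block-locked, so this preset is flagged
#'   (`attr(, "phasic")`) as unsuitable for block-design GLM mapping.
#'
#' @param name Preset name, one of `"corneal_mech"`, `"capsaicin"`,
#'   `"von_frey"`, `"whisker"`.
#' @param dt Indicator sampling interval (s).
#' @return A `fus_paradigm`.
#' @examples
#' p <- paradigm_preset("corneal_mech", dt = 1)
#' p$total_duration       # 220 s
#' sum(paradigm_indicator(p)$on) * p$dt  # 60 s of stimulation
#' @export
paradigm_preset <- function(name, dt = 0.1) {
  valid <- c("corneal_mech", "capsaicin", "von_frey", "whisker")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop(sprintf("unknown paradigm preset '%s'; valid presets are: %s",
                 as.character(name)[1],
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  p <- switch(name,
    corneal_mech = stimulus_paradigm(
      onsets = 30 + (0:5) * 30, durations = rep(10, 6),
      total_duration = 220, dt = dt),
    von_frey = stimulus_paradigm(
      onsets = 60 + (0:3) * 60, durations = rep(5, 4),
      total_duration = 305, dt = dt),
    whisker = stimulus_paradigm(
      onsets = 30 + (0:5) * 40, durations = rep(20, 6),
      total_duration = 280, dt = dt),
    capsaicin = {
      q <- stimulus_paradigm(onsets = 60, durations = 180,
                             total_duration = 300, dt = dt)
      attr(q, "phasic") <- TRUE
      q
    })
  attr(p, "preset") <- name
  p
}

#' Rasterise the binary stimulation indicator
#'
#' Samples the paradigm as a 0/1 indicator on the grid `t_i = (i - 1) * dt`,
#' with stimulation windows half-open (`[onset, onset + duration)`), so that
#' `sum(on) * dt` equals the total stimulated time.
#'
#' @param paradigm A `fus_paradigm`.
#' @param dt Sampling interval; defaults to the paradigm's own.
#' @return A tibble with columns `time` (s) and `on` (0/1).
#' @export
paradigm_indicator <- function(paradigm, dt = paradigm$dt) {
  n <- as.integer(round(paradigm$total_duration / dt))
  t <- (seq_len(n) - 1) * dt
  on <- rep(0, n)
  for (i in seq_along(paradigm$onsets)) {
    on[t >= paradigm$onsets[i] - 1e-9 &
       t < paradigm$onsets[i] + paradigm$durations[i] - 1e-9] <- 1
  }
  tibble::tibble(time = t, on = on)
}

# classify Power Doppler frames against the paradigm: a frame (one block,
# spanning [ (b-1)*dt_f, b*dt_f )) is "baseline" iff the indicator is
# strictly zero over its whole span, and "stim" iff it overlaps any
# stimulation window
classify_frames <- function(paradigm, n_frames, frame_interval) {
  ind <- paradigm_indicator(paradigm)
  starts <- (seq_len(n_frames) - 1) * frame_interval
  ends <- starts + frame_interval
  stim <- vapply(seq_len(n_frames), function(b) {
    any(ind$on[ind$time >= starts[b] - 1e-9 & ind$time < ends[b] - 1e-9] > 0)
  }, logical(1))
  stim
}
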