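#' Per-sample swing indicator from fused pressure words
#'
#' A sample is in the swing phase exactly when the foot is off the ground,
#' i.e. when every pressure sensor reads "no press". In practice Sensor 8
#' occasionally reports a "slightly pressed" level of 1 in late swing, just
#' before heel strike, which makes the fused word 1 instead of 0. The
#' threshold (default 1) absorbs exactly that artifact: the raw indicator is
#' \deqn{F(k) = 1 \iff p(k) \le \mathrm{threshold}.}
#'
#' The raw indicator is then debounced: swing runs shorter than
#' `min_swing` samples are flipped to stance, after which stance runs shorter
#' than `min_stance` samples are flipped to swing. The defaults (5 samples =
#' 0.1 s at 50 Hz) are well below physiological swing/stance durations, so
#' genuine phases are never suppressed.
#'
#' @param data An [insole_recording()] (needs a `pressure` column).
#' @param threshold Pressure-word cutoff; a word `<= threshold` is swing
#'   (default 1, tolerating the Sensor-8 late-swing artifact).
#' @param min_swing,min_stance Debounce run lengths in samples (default 5).
#' @return The input with an integer `swing` column (1 = swing) appended.
#' @export
swing_mask <- function(data, threshold = 1, min_swing = 5, min_stance = 5) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  if (min_swing < 1 || min_stance < 1) {
    stop("debounce lengths must be >= 1 sample", call. = FALSE)
  }
  f <- as.integer(data$pressure <= threshold)
  f <- flip_short_runs(f, value = 1L, min_len = min_swing)
  f <- flip_short_runs(f, value = 0L, min_len = min_stance)
  data$swing <- f
  data
}

# flip runs of `value` shorter than min_len to the opposite value
flip_short_runs <- function(f, value, min_len) {
  if (min_len <= 1L) return(f)
  r <- rle(f)
  short <- r$values == value & r$lengths < min_len
  r$values[short] <- 1L - value
  inverse.rle(r)
}

#' Extract stride segments (maximal swing runs) from a masked recording
#'
#' Each maximal run of `swing == 1` is one swing phase, i.e. one stride of
#' the instrumented foot. Runs touching either recording boundary are
#' incomplete (their integrals would be truncated) and are dropped with a
#' warning; the measurement protocol has subjects standing still before and
#' after the walk, so complete runs are the expected case.
#'
#' @param data A recording with a `swing` column (see [swing_mask()]).
#' @param fs Sampling frequency in Hz; defaults to the recording attribute.
#' @return A tibble with one row per stride: `stride`, `start_idx`,
#'   `end_idx` (1-based, inclusive), `start_time` (toe-off instant,
#'   `t[start_idx]`), `stop_time` (landing instant, `t[end_idx] + 1/fs`),
#'   `n_samples` and `duration` (s).
#' @export
stride_segments <- function(data, fs = NULL) {
  if (!("swing" %in% names(data))) {
    stop("no `swing` column; run swing_mask() first", call. = FALSE)
  }
  fs <- recording_fs(data, fs)
  f <- data$swing
  n <- length(f)
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  starts <- starts[keep]
  ends <- ends[keep]
  at_boundary <- starts == 1L | ends == n
  if (any(at_boundary)) {
    warning(sum(at_boundary),
            " incomplete swing run(s) touching the recording boundary dropped",
            call. = FALSE)
    starts <- starts[!at_boundary]
    ends <- ends[!at_boundary]
  }
  n_samples <- ends - starts + 1L
  tibble::tibble(
    stride = seq_along(starts),
    start_idx = starts,
    end_idx = ends,
    start_time = data$t[starts],
    stop_time = data$t[ends] + 1 / fs,
    n_samples = n_samples,
    duration = n_samples / fs
  )
}

#' Count strides
#'
#' The number of strides of the instrumented foot equals the number of
#' complete swing phases.
#'
#' @param segments A stride table from [stride_segments()].
#' @return Integer stride count.
#' @export
count_strides <- function(segments) {
  nrow(segments)
}
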