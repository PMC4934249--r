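#' Gate acceleration by the swing mask
#'
#' Zeroes the acceleration channels outside swing phases:
#' \eqn{\hat a(k) = F(k)\,a(k)} per axis, so stance samples contribute
#' exactly nothing to downstream integrals.
#'
#' @param data A recording with `ax, ay, az` and a `swing` column.
#' @return The input with gated `ax, ay, az`.
#' @export
mask_acceleration <- function(data) {
  if (!("swing" %in% names(data))) {
    stop("no `swing` column; run swing_mask() first", call. = FALSE)
  }
  for (axis in c("ax", "ay", "az")) {
    data[[axis]] <- data[[axis]] * data$swing
  }
  data
}

#' Double-integrate one stride's swing-phase acceleration
#'
#' Over the stride's samples \eqn{k = 1..N} the acceleration magnitude
#' \eqn{a[k] = \sqrt{a_x^2 + a_y^2 + a_z^2}} is integrated twice with
#' left-endpoint rectangular sums and the velocity reset to zero at swing
#' start (the foot is stationary in stance):
#' \deqn{v_{MAG}[k] = \sum_{j \le k} a[j]\,\Delta t, \qquad
#'       d_{MAG} = \sum_k v_{MAG}[k]\,\Delta t,}
#' and analogously \eqn{v_z, d_z} from the vertical channel alone.
#' \eqn{d_{MAG}} is the tracing displacement (path of the foot through the
#' air); \eqn{d_z} the vertical displacement. Their ratio
#' \eqn{d_{MAG}/|d_z|} is the amplitude-scale-invariant quantity the
#' distance estimator consumes. When \eqn{|d_z|} falls below `dz_epsilon`
#' the ratio is undefined and the stride is flagged.
#'
#' Rectangular (not trapezoidal) quadrature is deliberate: the calibration
#' coefficient absorbs the quadrature constant, and the simple sums match
#' the online, sample-by-sample formulation exactly.
#'
#' @param data Tibble with linear acceleration `ax, ay, az`.
#' @param segment One row of a [stride_segments()] table (or anything with
#'   `start_idx` and `end_idx`).
#' @param fs Sampling frequency in Hz; defaults to the recording attribute.
#' @param dz_epsilon Minimum `|dz|` in metres below which the stride is
#'   flagged (default 1e-3).
#' @return A one-row tibble with `d_mag`, `d_z`, `ratio`, `flagged` and
#'   list-columns `a_mag`, `v_mag`, `v_z` holding the per-sample series.
#' @export
integrate_stride <- function(data, segment, fs = NULL, dz_epsilon = 1e-3) {
  fs <- recording_fs(data, fs)
  start <- segment$start_idx[1]
  end <- segment$end_idx[1]
  if (is.na(start) || is.na(end) || start > end) {
    stop("empty stride segment", call. = FALSE)
  }
  if (start < 1 || end > nrow(data)) {
    stop("stride segment out of recording bounds", call. = FALSE)
  }
  dt <- 1 / fs
  idx <- start:end
  ax <- data$ax[idx]; ay <- data$ay[idx]; az <- data$az[idx]
  a_mag <- sqrt(ax^2 + ay^2 + az^2)
  v_mag <- cumsum(a_mag) * dt
  d_mag <- sum(v_mag) * dt
  v_z <- cumsum(az) * dt
  d_z <- sum(v_z) * dt
  flagged <- abs(d_z) < dz_epsilon
  tibble::tibble(
    d_mag = d_mag,
    d_z = d_z,
    ratio = if (flagged) NA_real_ else d_mag / abs(d_z),
    flagged = flagged,
    a_mag = list(a_mag),
    v_mag = list(v_mag),
    v_z = list(v_z)
  )
}

#' Per-stride double integrals for a whole stride table
#'
#' Applies [integrate_stride()] to every row of a stride table and binds the
#' results onto it.
#'
#' @inheritParams integrate_stride
#' @param segments A [stride_segments()] table.
#' @return `segments` with columns `d_mag`, `d_z`, `ratio`, `flagged` and
#'   the per-sample list-columns appended.
#' @export
stride_integrals <- function(data, segments, fs = NULL, dz_epsilon = 1e-3) {
  fs <- recording_fs(data, fs)
  ints <- purrr::map(seq_len(nrow(segments)), function(i) {
    integrate_stride(data, segments[i, ], fs = fs, dz_epsilon = dz_epsilon)
  })
  dplyr::bind_cols(segments, dplyr::bind_rows(ints))
}

#' Estimate walking distance from per-stride integrals
#'
#' The cumulative distance after stride `n` is
#' \deqn{d[n] = d[n-1] + K \, \frac{d_{MAG}[n]}{|d_z[n]|} + L_0, \qquad d[0]=0,}
#' where `K` is the calibrated scale coefficient (see [fit_K()]) and `L0` the
#' constant foot length added per stride. Equivalently, in batch form,
#' `total = K * sum(ratio) + N * L0`; the two are identical and the tests
#' assert it. Strides flagged for degenerate vertical displacement use the
#' median ratio of the unflagged strides of the same recording; if every
#' stride is flagged the estimate is undefined and an error is raised.
#'
#' @param data Tibble with linear acceleration `ax, ay, az` (and a `swing`
#'   column if `segments` is not supplied).
#' @param segments Optional [stride_segments()] table; computed from the
#'   `swing` column when `NULL`.
#' @param K Calibration coefficient (> 0).
#' @param L0 Foot length in metres added per stride (default 0.26).
#' @param dz_epsilon Minimum `|dz|` in metres (default 1e-3).
#' @param fs Sampling frequency in Hz; defaults to the recording attribute.
#' @return An object of class `gait_distance`: per-stride table (with
#'   cumulative `distance`), `total_distance`, `stride_count`. Has
#'   [tidy()], [glance()], [autoplot()] and print methods.
#' @export
estimate_distance <- function(data, segments = NULL, K = 1, L0 = 0.26,
                              dz_epsilon = 1e-3, fs = NULL) {
  if (!is.numeric(K) || K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (!is.numeric(L0) || L0 < 0) stop("`L0` must be >= 0", call. = FALSE)
  if (dz_epsilon <= 0) stop("`dz_epsilon` must be > 0", call. = FALSE)
  fs <- recording_fs(data, fs)
  if (is.null(segments)) segments <- stride_segments(data, fs = fs)
  if (nrow(segments) == 0) stop("no strides detected", call. = FALSE)
  segments <- normalize_segments(data, segments, fs)
  strides <- stride_integrals(data, segments, fs = fs,
                              dz_epsilon = dz_epsilon)
  if (all(strides$flagged)) {
    stop("degenerate vertical displacement: every stride has |dz| < ",
         dz_epsilon, call. = FALSE)
  }
  fallback <- median(strides$ratio[!strides$flagged])
  strides$ratio_used <- ifelse(strides$flagged, fallback, strides$ratio)
  strides$stride_distance <- K * strides$ratio_used + L0
  strides$distance <- cumsum(strides$stride_distance)
  structure(
    list(strides = strides,
         total_distance = strides$distance[nrow(strides)],
         stride_count = nrow(strides),
         K = K, L0 = L0, fs = fs),
    class = "gait_distance"
  )
}

#' @export
print.gait_distance <- function(x, ...) {
  cat(sprintf("Walking distance estimate: %.3f m over %d stride(s) (K = %g, L0 = %g m)\n",
              x$total_distance, x$stride_count, x$K, x$L0))
  n_flagged <- sum(x$strides$flagged)
  if (n_flagged > 0) {
    cat(sprintf("  %d stride(s) flagged for degenerate |dz|; median-ratio fallback used\n",
                n_flagged))
  }
  print(tidy(x), ...)
  invisible(x)
}

# fill in the timing columns when a bare start/end segment table is supplied
normalize_segments <- function(data, segments, fs) {
  segments <- tibble::as_tibble(segments)
  if (!("stride" %in% names(segments))) {
    segments$stride <- seq_len(nrow(segments))
  }
  if (!("n_samples" %in% names(segments))) {
    segments$n_samples <- segments$end_idx - segments$start_idx + 1L
  }
  if (!("start_time" %in% names(segments))) {
    segments$start_time <- data$t[segments$start_idx]
  }
  if (!("stop_time" %in% names(segments))) {
    segments$stop_time <- data$t[segments$end_idx] + 1 / fs
  }
  if (!("duration" %in% names(segments))) {
    segments$duration <- segments$n_samples / fs
  }
  segments
}

#' @describeIn estimate_distance Per-stride tibble: timings, `d_mag`, `d_z`,
#'   `ratio`, flag, per-stride and cumulative distance.
#' @param x A `gait_distance` object.
#' @param ... Unused.
#' @export
tidy.gait_distance <- function(x, ...) {
  dplyr::select(x$strides, "stride", "start_time", "stop_time", "duration",
                "d_mag", "d_z", "ratio", "flagged", "stride_distance",
                "distance")
}

#' @describeIn estimate_distance One-row summary: stride count, total
#'   distance, flagged-stride count, parameters.
#' @export
glance.gait_distance <- function(x, ...) {
  tibble::tibble(
    stride_count = x$stride_count,
    total_distance = x$total_distance,
    n_flagged = sum(x$strides$flagged),
    mean_stride = x$total_distance / x$stride_count,
    K = x$K, L0 = x$L0
  )
}
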