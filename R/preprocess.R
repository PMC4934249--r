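#' Separate gravity from raw acceleration
#'
#' Gravity is tracked per axis with the first-order exponential low-pass
#' recurrence
#' \deqn{g(t) = \alpha\,g(t-1) + (1-\alpha)\,a_{raw}(t)}
#' and linear acceleration is the complement \eqn{a(t) = a_{raw}(t) - g(t)}.
#' The smoothing constant defaults to \eqn{\alpha = 0.8}, which at 50 Hz
#' tracks the quasi-static gravity component while leaving gait-band motion
#' in the linear channel.
#'
#' The recurrence needs a starting value \eqn{g(0)}. By default it is seeded
#' with the first raw sample of each axis (`init = "first"`), which converges
#' immediately when the recording starts at rest in stance; `init = "zero"`
#' starts from 0 and is useful for analytic checks because it makes the
#' operator linear in the input.
#'
#' @param data An [insole_recording()] or tibble with `ax, ay, az` columns.
#' @param alpha Smoothing constant in (0, 1); default 0.8.
#' @param init Gravity initialisation policy: `"first"` (default) or `"zero"`.
#' @return The input with `ax, ay, az` replaced by linear acceleration and
#'   gravity estimates appended as `gx, gy, gz`.
#' @export
separate_gravity <- function(data, alpha = 0.8, init = c("first", "zero")) {
  init <- match.arg(init)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  for (axis in c("ax", "ay", "az")) {
    raw <- data[[axis]]
    g0 <- if (init == "first") raw[1] else 0
    # g[t] = alpha*g[t-1] + (1-alpha)*raw[t]  (first-order recursive filter)
    g <- as.numeric(stats::filter((1 - alpha) * raw, alpha,
                                  method = "recursive", init = g0))
    data[[axis]] <- raw - g
    data[[sub("a", "g", axis)]] <- g
  }
  data
}

#' Band-pass filter the linear acceleration channels
#'
#' Applies a Butterworth band-pass (default corners 5 and 10 Hz, order 2) to
#' `ax, ay, az`, forward-backward (`signal::filtfilt`) so the zero-phase
#' output stays time-aligned with the pressure-derived swing mask. Pressure
#' words are discrete states and are never filtered. The stage can be
#' disabled (`enabled = FALSE` returns the input unchanged): the 5-10 Hz
#' band sits above the dominant ~1-3 Hz gait band, so distance estimation on
#' clean signals is usually run with the stage off (see the package
#' vignette).
#'
#' @param data Tibble with `ax, ay, az` columns.
#' @param fc Length-2 numeric, band corner frequencies in Hz (default
#'   `c(5, 10)`).
#' @param order Butterworth order (default 2).
#' @param enabled If `FALSE`, pass through unchanged.
#' @param fs Sampling frequency in Hz; defaults to the recording attribute.
#' @return The input with filtered `ax, ay, az`.
#' @export
bandpass_accel <- function(data, fc = c(5, 10), order = 2, enabled = TRUE,
                           fs = NULL) {
  if (!enabled) return(data)
  fs <- recording_fs(data, fs)
  if (length(fc) != 2L || any(fc <= 0) || fc[1] >= fc[2]) {
    stop("`fc` must be increasing positive corner frequencies c(fc1, fc2)",
         call. = FALSE)
  }
  if (fc[2] >= fs / 2) {
    stop("upper corner fc2 = ", fc[2], " Hz must be below the Nyquist ",
         "frequency fs/2 = ", fs / 2, " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "pass")
  for (axis in c("ax", "ay", "az")) {
    data[[axis]] <- as.numeric(signal::filtfilt(bf, data[[axis]]))
  }
  data
}
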