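#' Run the full distance pipeline on one recording
#'
#' Chains the stages in measurement order: gravity separation, optional
#' band-pass, swing-mask thresholding, stride segmentation, swing gating and
#' per-stride double-integration distance. The result is a pure function of
#' the recording and the parameters.
#'
#' @param data An [insole_recording()].
#' @param params A [gait_params()] object.
#' @return A `gait_distance` object (see [estimate_distance()]).
#' @examples
#' sim <- simulate_walk(n_strides = 8, seed = 42)
#' est <- estimate_walk(sim$recording,
#'                      gait_params(K = 0.1, bandpass_enabled = FALSE))
#' glance(est)
#' @export
estimate_walk <- function(data, params = gait_params()) {
  validate_gait_params(params)
  data |>
    separate_gravity(alpha = params$alpha, init = params$gravity_init) |>
    bandpass_accel(fc = c(params$fc1, params$fc2),
                   order = params$bandpass_order,
                   enabled = params$bandpass_enabled, fs = params$fs) |>
    swing_mask(threshold = params$threshold, min_swing = params$min_swing,
               min_stance = params$min_stance) |>
    mask_acceleration() |>
    estimate_distance(K = params$K, L0 = params$L0,
                      dz_epsilon = params$dz_epsilon, fs = params$fs)
}

#' Run the pipeline on a recording file and print a report
#'
#' Thin file-level wrapper over [read_recording()] + [estimate_walk()] used
#' by the `gaitkit` command-line script. The sampling frequency of the
#' loaded recording overrides the config's `fs`.
#'
#' @param path Recording CSV path.
#' @param config A [gait_params()] object, a YAML config path, or `NULL` for
#'   defaults.
#' @param quiet Suppress the printed report.
#' @return The `gait_distance` result, invisibly when printing.
#' @export
run_pipeline <- function(path, config = NULL, quiet = FALSE) {
  params <- if (is.null(config)) {
    gait_params()
  } else if (inherits(config, "gait_params")) {
    config
  } else {
    read_gait_config(config)
  }
  rec <- read_recording(path)
  params$fs <- recording_fs(rec, NULL)
  est <- estimate_walk(rec, params)
  if (!quiet) print(est)
  invisible(est)
}
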