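#' Pipeline parameters
#'
#' Bundles every tunable of the insole pipeline with the measurement
#' system's defaults: 50 Hz sampling, gravity smoothing `alpha = 0.8`,
#' 5-10 Hz order-2 Butterworth band-pass, pressure threshold 1, 0.1 s
#' debounce, foot length `L0 = 0.26` m. `K = 1` is a placeholder until
#' calibrated with [fit_K()].
#'
#' @param fs Sampling frequency in Hz.
#' @param alpha Gravity-separation smoothing constant in (0, 1).
#' @param gravity_init `"first"` or `"zero"` (see [separate_gravity()]).
#' @param bandpass_enabled Apply the Butterworth band-pass? See
#'   [bandpass_accel()] for why distance work on clean signals usually
#'   disables it.
#' @param fc1,fc2 Band-pass corner frequencies in Hz.
#' @param bandpass_order Butterworth order.
#' @param threshold Pressure-word swing cutoff.
#' @param min_swing,min_stance Debounce lengths in samples.
#' @param K Distance scale coefficient.
#' @param L0 Foot length in metres.
#' @param dz_epsilon Minimum `|dz|` in metres.
#' @return A `gait_params` list.
#' @export
gait_params <- function(fs = 50, alpha = 0.8, gravity_init = "first",
                        bandpass_enabled = TRUE, fc1 = 5, fc2 = 10,
                        bandpass_order = 2, threshold = 1, min_swing = 5,
                        min_stance = 5, K = 1, L0 = 0.26, dz_epsilon = 1e-3) {
  p <- list(fs = fs, alpha = alpha, gravity_init = gravity_init,
            bandpass_enabled = isTRUE(bandpass_enabled), fc1 = fc1, fc2 = fc2,
            bandpass_order = bandpass_order, threshold = threshold,
            min_swing = min_swing, min_stance = min_stance, K = K, L0 = L0,
            dz_epsilon = dz_epsilon)
  validate_gait_params(p)
  structure(p, class = "gait_params")
}

validate_gait_params <- function(p) {
  stopifnot_msg(p$fs > 0, "fs must be > 0")
  stopifnot_msg(p$alpha > 0 && p$alpha < 1, "alpha must be in (0, 1)")
  stopifnot_msg(p$gravity_init %in% c("first", "zero"),
                "gravity_init must be 'first' or 'zero'")
  if (p$bandpass_enabled) {
    stopifnot_msg(p$fc1 > 0 && p$fc1 < p$fc2 && p$fc2 < p$fs / 2,
                  "need 0 < fc1 < fc2 < fs/2")
    stopifnot_msg(p$bandpass_order >= 1, "bandpass_order must be >= 1")
  }
  stopifnot_msg(p$threshold >= 0, "threshold must be >= 0")
  stopifnot_msg(p$min_swing >= 1 && p$min_stance >= 1,
                "debounce lengths must be >= 1")
  stopifnot_msg(p$K > 0, "K must be > 0")
  stopifnot_msg(p$L0 >= 0, "L0 must be >= 0")
  stopifnot_msg(p$dz_epsilon > 0, "dz_epsilon must be > 0")
  invisible(p)
}

stopifnot_msg <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
}

#' @export
print.gait_params <- function(x, ...) {
  cat("Gait pipeline parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write pipeline parameters as YAML
#'
#' The config document is a flat YAML mapping of the [gait_params()] fields;
#' unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return [read_gait_config()] returns a `gait_params` object;
#'   [write_gait_config()] returns `path` invisibly.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(gait_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("invalid configuration: unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(gait_params, vals)
}

#' @rdname read_gait_config
#' @param params A [gait_params()] object.
#' @export
write_gait_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
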