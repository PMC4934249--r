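#' Bundle recordings with reference distances
#'
#' Builds the labelled-walk table consumed by [fit_K()] and
#' [loocv_evaluate()]: one row per walk, the recording in a list-column and
#' its measured reference distance alongside.
#'
#' @param recordings A list of [insole_recording()] objects (a single
#'   recording is accepted).
#' @param reference_distance Reference distance(s) in metres, length 1 or
#'   `length(recordings)`.
#' @return A tibble with columns `walk`, `recording`, `reference_distance`.
#' @export
labelled_walks <- function(recordings, reference_distance) {
  if (inherits(recordings, "insole_recording")) recordings <- list(recordings)
  n <- length(recordings)
  reference_distance <- rep_len(reference_distance, n)
  stopifnot_msg(all(reference_distance > 0),
                "reference distances must be > 0")
  tibble::tibble(walk = seq_len(n), recording = recordings,
                 reference_distance = reference_distance)
}

# per-walk stride count and sum of per-stride ratios (flagged strides use
# the walk's median unflagged ratio, matching estimate_distance())
walk_summaries <- function(walks, params) {
  purrr::map_dfr(seq_len(nrow(walks)), function(i) {
    rec <- walks$recording[[i]]
    pre <- rec |>
      separate_gravity(alpha = params$alpha, init = params$gravity_init) |>
      bandpass_accel(fc = c(params$fc1, params$fc2),
                     order = params$bandpass_order,
                     enabled = params$bandpass_enabled, fs = params$fs) |>
      swing_mask(threshold = params$threshold, min_swing = params$min_swing,
                 min_stance = params$min_stance) |>
      mask_acceleration()
    segments <- stride_segments(pre, fs = params$fs)
    if (nrow(segments) == 0) {
      stop("no strides detected in walk ", walks$walk[i], call. = FALSE)
    }
    ints <- stride_integrals(pre, segments, fs = params$fs,
                             dz_epsilon = params$dz_epsilon)
    if (all(ints$flagged)) {
      stop("degenerate vertical displacement in walk ", walks$walk[i],
           call. = FALSE)
    }
    fallback <- median(ints$ratio[!ints$flagged])
    ratio <- ifelse(ints$flagged, fallback, ints$ratio)
    tibble::tibble(walk = walks$walk[i],
                   reference_distance = walks$reference_distance[i],
                   n_strides = nrow(segments),
                   sum_ratio = sum(ratio),
                   n_flagged = sum(ints$flagged))
  })
}

#' Calibrate the distance scale coefficient K
#'
#' For each labelled walk the coefficient that reproduces its reference
#' distance exactly follows from the batch form of the distance estimator:
#' \deqn{K_i = \frac{d^{(r)}_i - N_i L_0}{\sum_n \mathrm{ratio}_{i,n}},}
#' and the calibrated coefficient is the arithmetic mean of the per-walk
#' coefficients. Re-estimating a walk with its own `K_i` returns its
#' reference distance to floating-point accuracy (the tests assert this
#' identity).
#'
#' @param walks A [labelled_walks()] table (columns `walk`, `recording`,
#'   `reference_distance`).
#' @param params A [gait_params()] object (its `K` is ignored).
#' @return An object of class `gait_calibration` with elements `K`,
#'   `per_walk` (tibble of per-walk coefficients) and `params`. Has
#'   [tidy()], [glance()] and print methods.
#' @export
fit_K <- function(walks, params = gait_params()) {
  validate_gait_params(params)
  stopifnot_msg(nrow(walks) >= 1, "need at least one labelled walk")
  summ <- walk_summaries(walks, params)
  summ$K_walk <- (summ$reference_distance - summ$n_strides * params$L0) /
    summ$sum_ratio
  bad <- summ$sum_ratio <= 0 | summ$K_walk <= 0
  if (any(bad)) {
    stop("calibration failed for walk(s) ",
         paste(summ$walk[bad], collapse = ", "),
         ": non-positive ratio sum or coefficient", call. = FALSE)
  }
  structure(
    list(K = mean(summ$K_walk), per_walk = summ, params = params),
    class = "gait_calibration"
  )
}

#' @export
print.gait_calibration <- function(x, ...) {
  cat(sprintf("Calibrated distance coefficient K = %.6g (mean of %d walk coefficients, SD %.3g)\n",
              x$K, nrow(x$per_walk), sd(x$per_walk$K_walk)))
  invisible(x)
}

#' @describeIn fit_K Per-walk tibble with stride counts, ratio sums and
#'   per-walk coefficients.
#' @param x A `gait_calibration` object.
#' @param ... Unused.
#' @export
tidy.gait_calibration <- function(x, ...) {
  x$per_walk
}

#' @describeIn fit_K One-row summary: `K`, number of walks, coefficient SD.
#' @export
glance.gait_calibration <- function(x, ...) {
  tibble::tibble(K = x$K, n_walks = nrow(x$per_walk),
                 K_sd = sd(x$per_walk$K_walk), L0 = x$params$L0)
}

#' Leave-one-out evaluation of the calibrated distance estimator
#'
#' Standard LOOCV over a labelled-walk database: each walk is held out in
#' turn, the coefficient is calibrated on the remaining walks (mean of their
#' per-walk coefficients), and the held-out walk's distance is estimated
#' with that coefficient. Deterministic -- there is no randomness in the
#' fold structure. Summary statistics (mean, median, min, max, SD of the
#' estimates) and the mean relative error
#' \deqn{e = \frac{1}{N}\sum_i \frac{|d^{(m)}_i - d^{(r)}_i|}{d^{(r)}_i}}
#' are aggregated across folds.
#'
#' @inheritParams fit_K
#' @return An object of class `gait_evaluation` with per-fold `estimates`
#'   and a one-row `summary`. Has [tidy()], [glance()], [autoplot()] and
#'   print methods.
#' @export
loocv_evaluate <- function(walks, params = gait_params()) {
  validate_gait_params(params)
  stopifnot_msg(nrow(walks) >= 2, "LOOCV needs at least two walks")
  summ <- walk_summaries(walks, params)
  summ$K_walk <- (summ$reference_distance - summ$n_strides * params$L0) /
    summ$sum_ratio
  bad <- summ$sum_ratio <= 0 | summ$K_walk <= 0
  if (any(bad)) {
    stop("calibration failed for walk(s) ",
         paste(summ$walk[bad], collapse = ", "),
         ": non-positive ratio sum or coefficient", call. = FALSE)
  }
  n <- nrow(summ)
  folds <- purrr::map_dfr(seq_len(n), function(i) {
    K_train <- mean(summ$K_walk[-i])
    est <- K_train * summ$sum_ratio[i] + summ$n_strides[i] * params$L0
    tibble::tibble(walk = summ$walk[i],
                   reference_distance = summ$reference_distance[i],
                   K_train = K_train,
                   estimate = est,
                   rel_error = abs(est - summ$reference_distance[i]) /
                     summ$reference_distance[i])
  })
  new_gait_evaluation(folds, params)
}

#' Summary error statistics for a set of distance estimates
#'
#' Computes the evaluation-table statistics (mean, median, min, max, SD of
#' the estimates) and the mean relative error
#' \eqn{e = \frac{1}{N}\sum |d^{(m)}_i - d^{(r)}| / d^{(r)}} for estimates
#' against a common reference distance.
#'
#' @param estimates Numeric vector of estimated distances in metres.
#' @param reference Reference distance in metres (scalar, or one per
#'   estimate).
#' @return A `gait_evaluation` object (see [loocv_evaluate()]).
#' @examples
#' glance(error_stats(c(15, 17), 16))  # error = 0.0625
#' @export
error_stats <- function(estimates, reference) {
  stopifnot_msg(length(estimates) >= 1, "need at least one estimate")
  stopifnot_msg(all(reference > 0), "reference distance must be > 0")
  reference <- rep_len(reference, length(estimates))
  folds <- tibble::tibble(walk = seq_along(estimates),
                          reference_distance = reference,
                          K_train = NA_real_,
                          estimate = estimates,
                          rel_error = abs(estimates - reference) / reference)
  new_gait_evaluation(folds, NULL)
}

new_gait_evaluation <- function(folds, params) {
  summary <- tibble::tibble(
    n = nrow(folds),
    mean = mean(folds$estimate),
    median = median(folds$estimate),
    min = min(folds$estimate),
    max = max(folds$estimate),
    sd = if (nrow(folds) > 1) sd(folds$estimate) else NA_real_,
    error = mean(folds$rel_error)
  )
  structure(list(estimates = folds, summary = summary, params = params),
            class = "gait_evaluation")
}

#' @export
print.gait_evaluation <- function(x, ...) {
  cat(sprintf("Distance evaluation over %d walk(s):\n", x$summary$n))
  print(x$summary, ...)
  invisible(x)
}

#' @describeIn loocv_evaluate Per-fold tibble: reference, training
#'   coefficient, estimate, relative error.
#' @param x A `gait_evaluation` object.
#' @param ... Unused.
#' @export
tidy.gait_evaluation <- function(x, ...) {
  x$estimates
}

#' @describeIn loocv_evaluate One-row tibble with Mean / Median / Min / Max
#'   / SD of the estimates and the mean relative error.
#' @export
glance.gait_evaluation <- function(x, ...) {
  x$summary
}
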