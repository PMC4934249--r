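#' Construct an insole recording
#'
#' An insole recording is a tibble with one row per sample and columns
#' `t` (seconds since recording start), `ax`, `ay`, `az` (raw triaxial
#' acceleration, m/s^2) and `pressure` (the fused 16-bit pressure word, see
#' [encode_pressure()]). Samples must be uniformly spaced at `1/fs`;
#' resampling or gap repair is out of scope and violations are an input
#' error. The sampling frequency and optional metadata travel as attributes
#' so the tibble stays pipe-friendly.
#'
#' @param data A data frame with columns `t, ax, ay, az, pressure`.
#' @param fs Sampling frequency in Hz (default 50, the insole module's rate).
#' @param subject Optional subject label.
#' @param reference_distance Optional reference walking distance in metres
#'   (the labelled ground-truth distance of a calibration walk).
#' @param validate Check invariants (default `TRUE`).
#' @return A tibble of class `insole_recording` with attributes `fs`,
#'   `subject` and `reference_distance`.
#' @export
insole_recording <- function(data, fs = 50, subject = NULL,
                             reference_distance = NULL, validate = TRUE) {
  data <- tibble::as_tibble(data)
  required <- c("t", "ax", "ay", "az", "pressure")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("recording is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (validate) validate_recording(data, fs)
  data$pressure <- as.integer(data$pressure)
  structure(data,
            class = c("insole_recording", class(tibble::tibble())),
            fs = fs, subject = subject,
            reference_distance = reference_distance)
}

validate_recording <- function(data, fs) {
  if (nrow(data) < 2L) stop("a recording needs at least 2 samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  t <- data$t
  if (anyNA(t) || any(t < 0)) stop("timestamps must be non-negative", call. = FALSE)
  dt <- diff(t)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    stop("timestamps must be strictly increasing (violation at sample ",
         bad[1] + 1L, ")", call. = FALSE)
  }
  # uniform spacing at 1/fs within relative tolerance 1e-6
  off <- which(abs(dt - 1 / fs) > 1e-6 / fs)
  if (length(off) > 0) {
    stop("samples are not uniformly spaced at 1/fs = ", signif(1 / fs, 6),
         " s (violation at sample ", off[1] + 1L, ")", call. = FALSE)
  }
  p <- data$pressure
  if (anyNA(p) || any(p != floor(p)) || any(p < 0) || any(p > 65535)) {
    stop("pressure words must be integers in [0, 65535]", call. = FALSE)
  }
  for (axis in c("ax", "ay", "az")) {
    if (!is.numeric(data[[axis]]) || anyNA(data[[axis]])) {
      stop("acceleration column `", axis, "` must be numeric without NA",
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Sampling frequency of a recording
#'
#' Returns `fs` explicitly supplied, else the recording's `fs` attribute,
#' else the insole module default of 50 Hz.
#'
#' @param data A recording or any tibble derived from one.
#' @param fs Optional explicit override in Hz.
#' @return Sampling frequency in Hz.
#' @export
recording_fs <- function(data, fs = NULL) {
  fs %||% attr(data, "fs", exact = TRUE) %||% 50
}

meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Read an insole recording from CSV (+ optional JSON metadata sidecar)
#'
#' The on-disk format is a comma-separated file with mandatory header
#' `t,ax,ay,az,pressure` ('.' decimal, UTF-8). An optional sidecar
#' `<name>.meta.json` holds `{fs, subject, reference_distance_m}`; when it is
#' absent the sampling frequency defaults to 50 Hz. Malformed rows,
#' non-monotone timestamps and out-of-range pressure words are reported with
#' the offending line number.
#'
#' @param path Path to the recording CSV.
#' @return An [insole_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  data <- suppressWarnings(readr::read_csv(path,
                          col_types = readr::cols(
                            t = readr::col_double(),
                            ax = readr::col_double(),
                            ay = readr::col_double(),
                            az = readr::col_double(),
                            pressure = readr::col_double()
                          ),
                          progress = FALSE))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    # vroom reports the physical file line (header included)
    stop("parse error in ", path, " at line ", probs$row[1],
         ": expected ", probs$expected[1], call. = FALSE)
  }
  p <- data$pressure
  bad <- which(is.na(p) | p != floor(p) | p < 0 | p > 65535)
  if (length(bad) > 0) {
    stop("parse error in ", path, " at line ", bad[1] + 1L,
         ": pressure word out of [0, 65535]", call. = FALSE)
  }
  fs <- 50
  subject <- NULL
  reference <- NULL
  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    fs <- meta$fs %||% 50
    subject <- meta$subject
    reference <- meta$reference_distance_m
    if (!is.null(reference) && (length(reference) == 0 || is.na(reference))) {
      reference <- NULL
    }
  }
  tryCatch(
    insole_recording(data, fs = fs, subject = subject,
                     reference_distance = reference),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write an insole recording to CSV (+ JSON metadata sidecar)
#'
#' Writes the five-column CSV read back by [read_recording()] and a sidecar
#' `<name>.meta.json` with the sampling frequency and metadata. Integers
#' round-trip bit-exactly; floats round-trip to full double precision.
#'
#' @param data An [insole_recording()] (or compatible tibble).
#' @param path Output CSV path.
#' @param fs,subject,reference_distance Overrides for the recording's
#'   attributes.
#' @return `path`, invisibly.
#' @export
write_recording <- function(data, path, fs = NULL, subject = NULL,
                            reference_distance = NULL) {
  fs <- recording_fs(data, fs)
  subject <- subject %||% attr(data, "subject", exact = TRUE)
  reference <- reference_distance %||%
    attr(data, "reference_distance", exact = TRUE)
  out <- tibble::as_tibble(data)[c("t", "ax", "ay", "az", "pressure")]
  readr::write_csv(out, path, progress = FALSE)
  meta <- list(fs = fs,
               subject = if (is.null(subject)) NA_character_ else subject,
               reference_distance_m = if (is.null(reference)) NA_real_ else reference)
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @export
print.insole_recording <- function(x, ...) {
  fs <- recording_fs(x)
  cat(sprintf("# Insole recording: %d samples at %g Hz (%.2f s)\n",
              nrow(x), fs, nrow(x) / fs))
  subject <- attr(x, "subject", exact = TRUE)
  ref <- attr(x, "reference_distance", exact = TRUE)
  if (!is.null(subject)) cat("# subject:", subject, "\n")
  if (!is.null(ref)) cat(sprintf("# reference distance: %g m\n", ref))
  NextMethod()
}
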