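#' Encode eight 2-bit pressure levels into a fused 16-bit pressure word
#'
#' Each of the eight insole pressure sensors reports a 2-bit pressing level
#' in `{0, 1, 2, 3}`. The eight levels are packed into one 16-bit word with
#' Sensor 1 in the most significant bit pair (bits 15-14) and Sensor 8 in the
#' least significant pair (bits 1-0), i.e.
#' \deqn{w = \sum_{i=1}^{8} \ell_i \, 4^{\,8-i}.}
#' This is the word transmitted by the insole module instead of eight
#' separate values; a word of 0 means every sensor is off (foot in the air),
#' a word of 1 means only Sensor 8 is "slightly pressed".
#'
#' @param levels An integer vector of length 8 (one word), or an n x 8
#'   matrix / data frame of levels (one row per word). Levels must be in
#'   `{0, 1, 2, 3}`.
#' @return An integer vector of pressure words in `[0, 65535]`.
#' @seealso [decode_pressure()] for the inverse.
#' @examples
#' encode_pressure(c(0, 0, 0, 0, 0, 0, 0, 1))  # Sensor 8 slightly pressed -> 1
#' encode_pressure(c(1, 0, 0, 0, 0, 0, 0, 0))  # Sensor 1 level 1 -> 16384
#' @export
encode_pressure <- function(levels) {
  if (is.data.frame(levels)) levels <- as.matrix(levels)
  if (!is.matrix(levels)) {
    if (length(levels) != 8L) {
      stop("`levels` must contain exactly 8 sensor levels, got ",
           length(levels), call. = FALSE)
    }
    levels <- matrix(levels, nrow = 1L)
  }
  if (ncol(levels) != 8L) {
    stop("`levels` must have 8 columns (one per sensor), got ",
         ncol(levels), call. = FALSE)
  }
  storage.mode(levels) <- "double"
  if (anyNA(levels) || any(levels != floor(levels)) ||
      any(levels < 0) || any(levels > 3)) {
    stop("pressure levels must be integers in {0, 1, 2, 3}", call. = FALSE)
  }
  weights <- 4^(7:0)  # Sensor 1 most significant
  as.integer(drop(levels %*% weights))
}

#' Decode fused 16-bit pressure words into eight 2-bit sensor levels
#'
#' Inverse of [encode_pressure()]: unpacks each word into the eight per-sensor
#' pressing levels, Sensor 1 first.
#'
#' @param word An integer vector of pressure words, each in `[0, 65535]`.
#' @return An integer matrix with `length(word)` rows and 8 columns named
#'   `sensor1` ... `sensor8`.
#' @examples
#' decode_pressure(1)      # only sensor8 = 1
#' decode_pressure(65535)  # all sensors at level 3
#' @export
decode_pressure <- function(word) {
  word <- as.double(word)
  if (anyNA(word) || any(word != floor(word)) ||
      any(word < 0) || any(word > 65535)) {
    stop("pressure words must be integers in [0, 65535]", call. = FALSE)
  }
  out <- vapply(1:8, function(i) {
    as.integer((word %/% 4^(8 - i)) %% 4)
  }, integer(length(word)))
  out <- matrix(out, ncol = 8L,
                dimnames = list(NULL, paste0("sensor", 1:8)))
  out
}
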