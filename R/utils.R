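## Internal helpers shared across modules.

#' Convert linear power to decibels
#' @param p positive numeric vector of linear power values.
#' @return numeric vector, 10*log10(p).
#' @keywords internal
#' @noRd
toDb <- function(p) 10 * log10(p)

#' @noRd
fromDb <- function(db) 10^(db / 10)

## One-way amplitude attenuation factor for a dB/(cm*MHz) slope, frequency in
## Hz and path length in m. Round-trip signals pass this twice.
#' @noRd
attenAmplitude <- function(alphaDbCmMHz, freqHz, pathM) {
  dbLoss <- alphaDbCmMHz * (freqHz / 1e6) * (pathM * 100)
  10^(-dbLoss / 20)
}

#' Derive a stage sub-seed from a run seed
#'
#' Deterministic 32-bit sub-seed derivation so one run seed can drive many
#' independent random stages: `(seed * 48271 + offset * 16807) mod (2^31 - 1)`.
#'
#' @param seed integer run seed.
#' @param offset integer stage offset; different offsets give effectively
#'   independent sub-seeds.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, 101)
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483647)
}

#' @noRd
nextPow2 <- function(n) 2^ceiling(log2(n))

#' @noRd
hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

#' @noRd
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
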