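#' @include AllClasses.R
NULL

# Zero-phase Butterworth band-limiting.
#
# Band-pass is realized as a cascade of a zero-phase low-pass and a
# zero-phase high-pass stage: the cascade is numerically stable at the very
# low normalized edges (0.1 Hz at 1 kHz) where a single band-pass section in
# transfer-function form is not.

.designStages <- function(fs, band, order = 4L) {
  nyq <- fs / 2
  lo <- band[1L]
  hi <- band[2L]
  if (hi <= lo) stop("band edges must satisfy lower < upper")
  if (hi > nyq + 1e-12) stop("band upper edge must be below the Nyquist frequency")
  stages <- list()
  if (hi < nyq)
    stages <- c(stages, list(signal::butter(order, hi / nyq, type = "low")))
  if (lo > 0)
    stages <- c(stages, list(signal::butter(order, lo / nyq, type = "high")))
  if (!length(stages)) stop("band covers the whole spectrum; nothing to filter")
  stages
}

#' Zero-phase Butterworth band-limiting
#'
#' Filters a signal to the band \code{(lo, hi)} Hz with zero-phase
#' (forward-backward) Butterworth filtering, applied as a low-pass +
#' high-pass cascade. A lower edge of 0 gives a pure low-pass; an upper
#' edge at the Nyquist frequency gives a pure high-pass.
#'
#' @param x numeric vector, or channels x samples matrix (filtered per row).
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param order Butterworth order per stage (default 4).
#' @return filtered object of the same shape.
#' @export
bandLimit <- function(x, fs, band, order = 4L) {
  stages <- .designStages(fs, band, order)
  filt1 <- function(v) {
    for (st in stages) v <- signal::filtfilt(st, v)
    v
  }
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- filt1(x[i, ])
    out
  } else filt1(x)
}

# White-noise variance gain of the zero-phase cascade: mean over a uniform
# frequency grid of the squared overall magnitude response. filtfilt applies
# |H(f)|^2 per stage, so the power transfer is prod |H_k|^4.
.bandGainCache <- new.env(parent = emptyenv())

.bandVarianceGain <- function(fs, band, order = 4L, nGrid = 4096L) {
  key <- paste(fs, band[1L], band[2L], order, sep = "|")
  hit <- .bandGainCache[[key]]
  if (!is.null(hit)) return(hit)
  stages <- .designStages(fs, band, order)
  w <- seq(0, pi, length.out = nGrid)
  mag2 <- rep(1, nGrid)
  for (st in stages) {
    h <- signal::freqz(st$b, st$a, region = NULL, n = w)$h
    mag2 <- mag2 * Mod(h)^2   # one zero-phase stage: |H|^2
  }
  gain <- mean(mag2^2)
  .bandGainCache[[key]] <- gain
  gain
}

# Band-limit and rescale to (approximately) unit variance for unit-variance
# white-noise input, using the analytic variance gain of the cascade.
.unitBandNoise <- function(x, fs, band, order = 4L) {
  bandLimit(x, fs, band, order) / sqrt(.bandVarianceGain(fs, band, order))
}

# --- frequency-domain application of the zero-phase Butterworth magnitude ---
#
# The synthetic generator applies the cascade's zero-phase magnitude
# response exactly at the epoch's DFT frequencies (circular convolution).
# This avoids per-channel time-domain filtering cost and edge transients,
# and makes the unit-variance normalization of generated components exact.

.fftMultiplierCache <- new.env(parent = emptyenv())

.fftBandMultiplier <- function(n, fs, band, order = 4L) {
  key <- paste(n, fs, band[1L], band[2L], order, sep = "|")
  hit <- .fftMultiplierCache[[key]]
  if (!is.null(hit)) return(hit)
  stages <- .designStages(fs, band, order)
  f <- (seq_len(n) - 1L) / n          # cycles/sample
  f <- pmin(f, 1 - f)                 # fold to [0, 1/2]
  w <- 2 * pi * f
  mult <- rep(1, n)
  for (st in stages) {
    h <- signal::freqz(st$b, st$a, region = NULL, n = w)$h
    mult <- mult * Mod(h)^2           # zero-phase stage: |H|^2
  }
  out <- list(mult = mult, varGain = mean(mult^2))
  .fftMultiplierCache[[key]] <- out
  out
}

# Filter rows of a channels x samples matrix (or a vector) to `band`,
# normalized so unit-variance white noise in gives unit variance out.
.fftUnitBandNoise <- function(x, fs, band, order = 4L) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  m <- .fftBandMultiplier(n, fs, band, order)
  X <- stats::mvfft(t(x)) * m$mult
  out <- t(Re(stats::mvfft(X, inverse = TRUE))) / (n * sqrt(m$varGain))
  if (vec) out[1L, ] else out
}
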