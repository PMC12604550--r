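#' @include AllClasses.R AllGenerics.R filters.R recording-methods.R
NULL

#' Low-pass filter and downsample a raw recording
#'
#' Zero-phase (forward-backward) Butterworth low-pass at \code{cutoff}
#' followed by decimation by an integer factor. The default reproduces the
#' standard LFP extraction: 250 Hz third-order low-pass on 30 kHz raw data,
#' downsampled to 1 kHz. No extra anti-alias stage is applied: the low-pass
#' already bounds content below the output Nyquist for the default
#' parameters.
#'
#' @param raw a [Recording-class] or channels x samples matrix.
#' @param cutoff low-pass cutoff in Hz (default 250).
#' @param order Butterworth order (default 3).
#' @param fsOut output sampling rate in Hz (default 1000); must divide the
#'   input rate.
#' @param fs input sampling rate (required when \code{raw} is a matrix).
#' @return a [Recording-class] at \code{fsOut}.
#' @export
lowpassDownsample <- function(raw, cutoff = 250, order = 3L, fsOut = 1000,
                              fs = NULL) {
  if (is(raw, "Recording")) {
    fs <- samplingRate(raw)
    sig <- signalMatrix(raw)
    ids <- channelIds(raw)
    valid <- validMask(raw)
    excl <- excludedChannels(raw)
  } else {
    if (is.null(fs)) stop("fs required for matrix input")
    sig <- as.matrix(raw)
    ids <- sprintf("ch%03d", seq_len(nrow(sig)))
    valid <- rep(TRUE, ncol(sig))
    excl <- character()
  }
  if (fs < 2 * cutoff) stop("input rate must be at least twice the cutoff")
  factor <- fs / fsOut
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs must be an integer multiple of fsOut")
  factor <- as.integer(round(factor))
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- sig
  for (i in seq_len(nrow(sig))) out[i, ] <- signal::filtfilt(flt, sig[i, ])
  keep <- seq(1L, ncol(sig), by = factor)
  # an output sample is valid iff all raw samples it summarizes are valid
  vOut <- vapply(keep, function(k) {
    all(valid[k:min(ncol(sig), k + factor - 1L)])
  }, logical(1))
  newRecording(out[, keep, drop = FALSE], fsOut, channelIds = ids,
    valid = vOut, excludedChannels = excl)
}

#' Z-score each channel over valid samples
#'
#' Centers and scales every channel to mean 0 and standard deviation 1,
#' computed over mask-valid samples only. Channels with zero variance are
#' flagged excluded (not an error) and left unscaled.
#'
#' @param rec a [Recording-class].
#' @return the z-scored recording, with \code{excludedChannels} extended by
#'   any zero-variance channels.
#' @export
zscoreChannels <- function(rec) {
  stopifnot(is(rec, "Recording"))
  sig <- rec@signal
  ok <- rec@valid
  if (!any(ok)) stop("no valid samples to z-score over")
  excl <- rec@excludedChannels
  for (i in seq_len(nrow(sig))) {
    v <- sig[i, ok]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      excl <- union(excl, rec@channelIds[i])
      next
    }
    sig[i, ] <- (sig[i, ] - mean(v)) / s
  }
  initialize(rec, signal = sig, excludedChannels = excl, zscored = TRUE)
}

#' Partition a recording into non-overlapping epochs
#'
#' Builds the contiguous epoch grid; a trailing partial epoch is discarded,
#' and any epoch overlapping an invalid sample is flagged invalid (and is
#' excluded from all downstream statistics).
#'
#' @param rec a [Recording-class].
#' @param epochS epoch duration in seconds (default 10); \code{epochS * fs}
#'   must be an integer.
#' @return an [EpochGrid-class].
#' @export
buildEpochGrid <- function(rec, epochS = 10) {
  stopifnot(is(rec, "Recording"))
  fs <- samplingRate(rec)
  len <- epochS * fs
  if (abs(len - round(len)) > 1e-9)
    stop("epochS * fs must be an integer number of samples")
  len <- as.integer(round(len))
  nEp <- nSamples(rec) %/% len
  if (nEp == 0L) warning("epoch longer than recording; zero epochs")
  starts <- seq_len(nEp) * len - len + 1L
  valid <- vapply(starts, function(s) all(rec@valid[s:(s + len - 1L)]),
    logical(1))
  new("EpochGrid", epochS = epochS, fs = fs, epochLength = len,
    starts = as.integer(starts), valid = valid)
}

#' Virtual LFP: channel-average signal
#'
#' Sample-wise mean of the z-scored, non-excluded channels; a single series
#' summarizing the whole array, used for spectral sleep staging.
#'
#' @param rec a z-scored [Recording-class].
#' @return numeric vector of length \code{nSamples(rec)}.
#' @export
makeVirtualLFP <- function(rec) {
  stopifnot(is(rec, "Recording"))
  keep <- .keptChannels(rec)
  if (!length(keep)) stop("all channels excluded; no virtual LFP")
  colMeans(rec@signal[keep, , drop = FALSE])
}
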