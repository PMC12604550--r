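#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Recording
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channelIds channel identifiers (default \code{ch001 ...}).
#' @param valid per-sample validity mask (default all valid).
#' @param excludedChannels channels excluded from analysis.
#' @param zscored whether the signal is already z-scored.
#' @return a [Recording-class].
#' @export
newRecording <- function(signal, fs, channelIds = NULL, valid = NULL,
                         excludedChannels = character(), zscored = FALSE) {
  signal <- as.matrix(signal)
  if (is.null(channelIds)) channelIds <- sprintf("ch%03d", seq_len(nrow(signal)))
  if (is.null(valid)) valid <- rep(TRUE, ncol(signal))
  new("Recording", signal = signal, fs = fs, channelIds = channelIds,
    valid = valid, excludedChannels = excludedChannels, zscored = zscored)
}

#' @rdname nChannels
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@signal))

#' @rdname nChannels
#' @export
setMethod("nSamples", "Recording", function(x) ncol(x@signal))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)

#' @rdname channelIds
#' @export
setMethod("channelIds", "Recording", function(x) x@channelIds)

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "Recording", function(x) x@signal)

#' @rdname validMask
#' @export
setMethod("validMask", "Recording", function(x) x@valid)

#' @rdname excludedChannels
#' @export
setMethod("excludedChannels", "Recording", function(x) x@excludedChannels)

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d channels x %d samples at %g Hz (%.1f s)\n",
    nChannels(object), nSamples(object), object@fs,
    nSamples(object) / object@fs))
  nbad <- sum(!object@valid)
  cat(sprintf("  invalid samples: %d (%.2f%%)%s\n", nbad,
    100 * nbad / max(1L, nSamples(object)),
    if (object@zscored) "; z-scored" else ""))
  if (length(object@excludedChannels))
    cat("  excluded channels:",
      paste(object@excludedChannels, collapse = ", "), "\n")
})

#' Retained (non-excluded) channel indices
#' @noRd
.keptChannels <- function(rec) {
  which(!(rec@channelIds %in% rec@excludedChannels))
}

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochGrid", function(x) length(x@starts))

#' @rdname epochStarts
#' @export
setMethod("epochStarts", "EpochGrid", function(x) x@starts)

#' @rdname validEpochs
#' @export
setMethod("validEpochs", "EpochGrid", function(x) x@valid)

setMethod("show", "EpochGrid", function(object) {
  cat(sprintf("EpochGrid: %d epochs of %g s (%d samples), %d valid\n",
    nEpochs(object), object@epochS, object@epochLength, sum(object@valid)))
})

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "DistanceCorrelation", function(x) nrow(x@z))

#' @rdname zMatrix
#' @export
setMethod("zMatrix", "DistanceCorrelation", function(x) x@z)

#' @rdname binCounts
#' @export
setMethod("binCounts", "DistanceCorrelation", function(x) x@counts)

#' @rdname binDistances
#' @export
setMethod("binDistances", "DistanceCorrelation", function(x) x@binUpperUm)

#' @rdname epochIndices
#' @export
setMethod("epochIndices", "DistanceCorrelation", function(x) x@epochIndex)

setMethod("show", "DistanceCorrelation", function(object) {
  cat(sprintf(
    "DistanceCorrelation (%s): %d epochs x %d bins (upper edges %s um)\n",
    object@band, nrow(object@z), ncol(object@z),
    paste(object@binUpperUm, collapse = ", ")))
})

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "GroundTruth", function(x) x@states)

#' @rdname dropoutIntervals
#' @export
setMethod("dropoutIntervals", "GroundTruth", function(x) x@dropouts)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d epochs of %g s; states: %s; %d dropouts\n",
    length(object@states), object@epochS,
    paste(sprintf("%s=%d", names(table(object@states)),
      as.integer(table(object@states))), collapse = " "),
    nrow(object@dropouts)))
})
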