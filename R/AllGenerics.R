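#' @include AllClasses.R
NULL

#' Number of channels / samples in a container
#'
#' @param x a [Recording-class] or [ArrayLayout-class].
#' @return integer count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate accessor
#' @param x a [Recording-class].
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel identifier accessor
#' @param x a [Recording-class] or [ArrayLayout-class].
#' @return character vector of channel ids.
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' Signal matrix accessor
#' @param x a [Recording-class].
#' @return channels x samples numeric matrix.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' Per-sample validity mask accessor
#' @param x a [Recording-class].
#' @return logical vector, FALSE over artifact samples.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Excluded channel accessor
#' @param x a [Recording-class].
#' @return character vector of excluded channel ids.
#' @export
setGeneric("excludedChannels", function(x) standardGeneric("excludedChannels"))

#' Electrode position accessor
#' @param x an [ArrayLayout-class].
#' @return nWired x 2 matrix of positions (um).
#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))

#' Number of epochs in a grid or result
#' @param x an [EpochGrid-class] or [DistanceCorrelation-class].
#' @return integer count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Epoch start samples accessor
#' @param x an [EpochGrid-class].
#' @return integer vector of 1-based start samples.
#' @export
setGeneric("epochStarts", function(x) standardGeneric("epochStarts"))

#' Epoch validity accessor
#' @param x an [EpochGrid-class].
#' @return logical vector, one flag per epoch.
#' @export
setGeneric("validEpochs", function(x) standardGeneric("validEpochs"))

#' Mean Fisher z matrix accessor
#' @param x a [DistanceCorrelation-class].
#' @return epochs x bins matrix of mean Fisher z values.
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' Per-bin observation count accessor
#' @param x a [DistanceCorrelation-class].
#' @return epochs x bins matrix of pair counts.
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Nominal bin distance accessor
#' @param x a [DistanceCorrelation-class].
#' @return numeric vector of bin upper edges (um).
#' @export
setGeneric("binDistances", function(x) standardGeneric("binDistances"))

#' Epoch index accessor
#' @param x a [DistanceCorrelation-class].
#' @return integer vector of epoch indices the rows describe.
#' @export
setGeneric("epochIndices", function(x) standardGeneric("epochIndices"))

#' Per-epoch state label accessor
#' @param x a [GroundTruth-class].
#' @return character vector of state labels.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' Dropout interval accessor
#' @param x a [GroundTruth-class].
#' @return data.frame with columns start_s, end_s.
#' @export
setGeneric("dropoutIntervals", function(x) standardGeneric("dropoutIntervals"))

#' Expected pairwise correlation profile of a synthetic state
#'
#' Closed-form expected inter-channel Pearson correlation at distance
#' \code{d} implied by a generator parameterization: with per-band global,
#' spatial and local amplitudes (sg, ss, sn) and spatial length constant
#' ell,
#' \deqn{\rho^*(d) = \frac{\sum_b sg_b^2 + ss_b^2 e^{-d/\ell}}{\sum_b sg_b^2 + ss_b^2 + sn_b^2}.}
#'
#' @param x a [GroundTruth-class] or [generatorParams()] list.
#' @param state state label.
#' @param d distances in micrometres.
#' @return expected correlation at each distance.
#' @export
setGeneric("expectedCorrelation",
  function(x, state, d) standardGeneric("expectedCorrelation"))
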