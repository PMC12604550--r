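#' @import methods
NULL

#' Sleep state labels used throughout the package
#'
#' Epochs are classified as slow-wave sleep (\code{"SWS"}), REM or awake
#' (\code{"REM_AWAKE"}), or an intermediate/transitional state
#' (\code{"NULL"}).
#'
#' @export
SLEEP_STATES <- c("SWS", "REM_AWAKE", "NULL")

#' Planar electrode array geometry
#'
#' Regular-grid electrode layout (a Utah array by default: 10 x 10 sites at
#' 400 um pitch with the four corner sites unwired, leaving 96 electrodes).
#' All pairwise electrode distances derive from this object.
#'
#' @slot pitchUm grid pitch in micrometres.
#' @slot nRows,nCols grid dimensions.
#' @slot wired logical matrix (nRows x nCols); TRUE where a site carries an
#'   electrode.
#' @slot positions numeric matrix (nWired x 2, columns \code{x}, \code{y})
#'   of electrode positions in micrometres.
#' @slot channelIds character vector of channel identifiers, one per wired
#'   electrode.
#'
#' @seealso [utahArrayLayout()], [electrodeDistances()]
#' @export
setClass("ArrayLayout",
  representation(
    pitchUm = "numeric",
    nRows = "integer",
    nCols = "integer",
    wired = "matrix",
    positions = "matrix",
    channelIds = "character"
  )
)

setValidity("ArrayLayout", function(object) {
  msg <- character()
  if (length(object@pitchUm) != 1L || object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (sum(object@wired) != nrow(object@positions))
    msg <- c(msg, "number of wired sites must equal number of positions")
  if (nrow(object@positions) != length(object@channelIds))
    msg <- c(msg, "one channel id per wired electrode required")
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "positions must have columns x and y")
  # positions must lie on the pitch grid
  offgrid <- abs(object@positions / object@pitchUm -
    round(object@positions / object@pitchUm)) > 1e-9
  if (any(offgrid))
    msg <- c(msg, "positions must lie on the regular pitch grid")
  if (anyDuplicated(object@positions) > 0)
    msg <- c(msg, "duplicate electrode positions")
  if (length(msg)) msg else TRUE
})

#' Multichannel signal block
#'
#' A channels x samples signal matrix with its sampling rate, channel
#' identifiers, a per-sample validity mask (FALSE over dropout/artifact
#' intervals) and a set of excluded channels (e.g. zero-variance or broken
#' electrodes).
#'
#' @slot signal numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelIds character vector, one per row of \code{signal}.
#' @slot valid logical vector, one per sample; FALSE marks artifact samples.
#' @slot excludedChannels character vector of channel ids excluded from
#'   analysis.
#' @slot zscored logical; TRUE once channels have been z-scored.
#'
#' @seealso [zscoreChannels()], [buildEpochGrid()], [makeVirtualLFP()]
#' @export
setClass("Recording",
  representation(
    signal = "matrix",
    fs = "numeric",
    channelIds = "character",
    valid = "logical",
    excludedChannels = "character",
    zscored = "logical"
  ),
  prototype(excludedChannels = character(), zscored = FALSE)
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@signal) != length(object@channelIds))
    msg <- c(msg, "one channel id per signal row required")
  if (ncol(object@signal) != length(object@valid))
    msg <- c(msg, "validity mask must have one entry per sample")
  if (!all(object@excludedChannels %in% object@channelIds))
    msg <- c(msg, "excludedChannels must be a subset of channelIds")
  if (length(msg)) msg else TRUE
})

#' Non-overlapping contiguous epoch grid
#'
#' Partition of a recording into non-overlapping, contiguous epochs of fixed
#' duration. A trailing partial epoch is discarded. An epoch is valid iff
#' every sample inside it is mask-valid.
#'
#' @slot epochS epoch duration in seconds.
#' @slot fs sampling rate in Hz.
#' @slot epochLength samples per epoch.
#' @slot starts integer vector of 1-based start samples.
#' @slot valid logical flag per epoch.
#'
#' @seealso [buildEpochGrid()]
#' @export
setClass("EpochGrid",
  representation(
    epochS = "numeric",
    fs = "numeric",
    epochLength = "integer",
    starts = "integer",
    valid = "logical"
  )
)

setValidity("EpochGrid", function(object) {
  msg <- character()
  if (length(object@starts) != length(object@valid))
    msg <- c(msg, "one validity flag per epoch required")
  if (length(object@starts) > 1L &&
      any(diff(object@starts) != object@epochLength))
    msg <- c(msg, "epochs must be contiguous and non-overlapping")
  if (length(msg)) msg else TRUE
})

#' Distance-binned correlation functions
#'
#' Per-epoch correlation-by-distance functions: the count-weighted mean
#' Fisher z-transformed pairwise correlation within half-open distance bins
#' \code{(lower, upper]}, pooled over source electrodes, together with the
#' number of electrode-pair observations per bin.
#'
#' @slot z numeric matrix, epochs x bins, of mean Fisher z values (NA where
#'   a bin has no observations).
#' @slot counts integer matrix, epochs x bins, of pair observations (each
#'   pair counted once from each of its two source electrodes).
#' @slot binUpperUm numeric vector of bin upper edges in micrometres; the
#'   upper edge is the nominal distance of the bin.
#' @slot epochIndex integer indices of the epochs (into the epoch grid) each
#'   row describes.
#' @slot epochS epoch duration in seconds.
#' @slot nSamples samples per epoch (used for analytic confidence
#'   intervals).
#' @slot band character label, \code{"broadband"} or a narrowband name.
#'
#' @seealso [distanceCorrelations()], [fitExponential()]
#' @export
setClass("DistanceCorrelation",
  representation(
    z = "matrix",
    counts = "matrix",
    binUpperUm = "numeric",
    epochIndex = "integer",
    epochS = "numeric",
    nSamples = "integer",
    band = "character"
  ),
  prototype(band = "broadband")
)

setValidity("DistanceCorrelation", function(object) {
  msg <- character()
  if (!identical(dim(object@z), dim(object@counts)))
    msg <- c(msg, "z and counts must have identical dimensions")
  if (ncol(object@z) != length(object@binUpperUm))
    msg <- c(msg, "one bin edge per column required")
  if (nrow(object@z) != length(object@epochIndex))
    msg <- c(msg, "one epoch index per row required")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(is.finite(object@z[object@counts == 0L])))
    msg <- c(msg, "bins with zero count must carry NA means")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a synthetic session
#'
#' Everything the generator knows about a synthetic session: the state of
#' each epoch, the generative parameter set, and the injected dropout
#' intervals. The expected correlation profile per state is available
#' through [expectedCorrelation()].
#'
#' @slot states character vector of per-epoch state labels.
#' @slot params the [generatorParams()] list used.
#' @slot dropouts data.frame with columns \code{start_s}, \code{end_s}.
#' @slot epochS epoch duration in seconds.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [generateSession()], [expectedCorrelation()]
#' @export
setClass("GroundTruth",
  representation(
    states = "character",
    params = "list",
    dropouts = "data.frame",
    epochS = "numeric",
    fs = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (!all(object@states %in% SLEEP_STATES))
    "states must be in SLEEP_STATES" else TRUE
})
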