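#' @include AllClasses.R recording-methods.R synthetic.R
NULL

#' Read and write recordings
#'
#' A recording is stored as a directory holding an Arrow IPC (feather)
#' table \code{signal.feather} -- one column per channel plus a logical
#' \code{.valid} mask column -- and a JSON sidecar \code{meta.json} with
#' the sampling rate, channel ids, excluded channels and z-scoring flag.
#' The round trip is lossless.
#'
#' @param rec a [Recording-class].
#' @param path directory to write to / read from (created if needed).
#' @return \code{writeRecording} returns \code{path} invisibly;
#'   \code{readRecording} returns the [Recording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(t(rec@signal))
  names(tab) <- rec@channelIds
  tab$.valid <- rec@valid
  arrow::write_feather(tab, file.path(path, "signal.feather"))
  meta <- list(fs = rec@fs, channelIds = rec@channelIds,
    excludedChannels = rec@excludedChannels, zscored = rec@zscored)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
    file.path(path, "meta.json"))
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  tab <- as.data.frame(arrow::read_feather(file.path(path, "signal.feather")))
  valid <- tab$.valid
  sig <- t(as.matrix(tab[meta$channelIds]))
  dimnames(sig) <- NULL
  newRecording(sig, meta$fs, channelIds = meta$channelIds, valid = valid,
    excludedChannels = as.character(meta$excludedChannels),
    zscored = isTRUE(meta$zscored))
}

#' Read and write array layouts as JSON
#'
#' @param layout an [ArrayLayout-class].
#' @param path JSON file path.
#' @return \code{writeLayout} returns \code{path} invisibly;
#'   \code{readLayout} the [ArrayLayout-class].
#' @export
writeLayout <- function(layout, path) {
  stopifnot(is(layout, "ArrayLayout"))
  obj <- list(pitchUm = layout@pitchUm, nRows = layout@nRows,
    nCols = layout@nCols, wired = as.vector(layout@wired))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeLayout
#' @export
readLayout <- function(path) {
  obj <- jsonlite::fromJSON(path)
  utahArrayLayout(nRows = obj$nRows, nCols = obj$nCols,
    pitchUm = obj$pitchUm,
    unwired = matrix(obj$wired, obj$nRows, obj$nCols))
}

#' Read and write distance-correlation results as CSV
#'
#' Long-format table with one row per epoch per bin (columns \code{epoch},
#' \code{bin_upper_um}, \code{mean_z}, \code{count}, plus the constant
#' columns \code{epoch_s}, \code{n_samples}, \code{band} needed to rebuild
#' the object losslessly).
#'
#' @param fn a [DistanceCorrelation-class].
#' @param path CSV file path.
#' @return \code{writeDistanceCorrelation} returns \code{path} invisibly;
#'   \code{readDistanceCorrelation} the rebuilt object.
#' @export
writeDistanceCorrelation <- function(fn, path) {
  stopifnot(is(fn, "DistanceCorrelation"))
  long <- data.frame(
    epoch = rep(fn@epochIndex, each = length(fn@binUpperUm)),
    bin_upper_um = rep(fn@binUpperUm, times = length(fn@epochIndex)),
    mean_z = as.vector(t(fn@z)),
    count = as.vector(t(fn@counts)),
    epoch_s = fn@epochS, n_samples = fn@nSamples, band = fn@band)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceCorrelation
#' @export
readDistanceCorrelation <- function(path) {
  long <- utils::read.csv(path)
  edges <- sort(unique(long$bin_upper_um))
  epochs <- unique(long$epoch)
  long <- long[order(match(long$epoch, epochs),
    match(long$bin_upper_um, edges)), ]
  z <- matrix(long$mean_z, length(epochs), length(edges), byrow = TRUE)
  counts <- matrix(as.integer(long$count), length(epochs), length(edges),
    byrow = TRUE)
  new("DistanceCorrelation", z = z, counts = counts, binUpperUm = edges,
    epochIndex = as.integer(epochs), epochS = long$epoch_s[1L],
    nSamples = as.integer(long$n_samples[1L]), band = long$band[1L])
}

#' Read and write ground truth
#'
#' Stored as a directory with \code{epochs.csv} (epoch_index, t_start_s,
#' state), \code{dropouts.csv} and \code{params.json}.
#'
#' @param truth a [GroundTruth-class].
#' @param path directory path.
#' @return \code{writeGroundTruth} returns \code{path} invisibly;
#'   \code{readGroundTruth} the rebuilt object.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ep <- data.frame(epoch_index = seq_along(truth@states),
    t_start_s = (seq_along(truth@states) - 1L) * truth@epochS,
    state = truth@states)
  utils::write.csv(ep, file.path(path, "epochs.csv"), row.names = FALSE)
  utils::write.csv(truth@dropouts, file.path(path, "dropouts.csv"),
    row.names = FALSE)
  # named amplitude vectors must become lists: jsonlite serializes named
  # atomic vectors as plain arrays, dropping the names
  params <- truth@params
  params$states <- lapply(params$states, function(st) {
    st$amp <- lapply(st$amp, as.list)
    st
  })
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA),
    file.path(path, "params.json"))
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  ep <- utils::read.csv(file.path(path, "epochs.csv"))
  dr <- utils::read.csv(file.path(path, "dropouts.csv"))
  if (!nrow(dr)) dr <- data.frame(start_s = numeric(), end_s = numeric())
  # simplifyVector = FALSE: jsonlite otherwise drops the names of the
  # amplitude vectors
  raw <- jsonlite::fromJSON(file.path(path, "params.json"),
    simplifyVector = FALSE)
  params <- generatorParams(
    fs = raw$fs, epochS = raw$epochS,
    bands = lapply(raw$bands, function(b) unlist(b)),
    states = lapply(raw$states, function(st) {
      out <- list(ellUm = st$ellUm)
      if (!is.null(st$ellJitterSd)) out$ellJitterSd <- st$ellJitterSd
      out$amp <- lapply(st$amp, unlist)
      out
    }),
    transition = matrix(unlist(raw$transition), 3L, 3L, byrow = TRUE,
      dimnames = list(SLEEP_STATES, SLEEP_STATES)),
    dropoutRateHz = raw$dropoutRateHz, dropoutMedianS = raw$dropoutMedianS,
    dropoutSdlog = raw$dropoutSdlog, burstiness = raw$burstiness,
    burstGapS = raw$burstGapS)
  new("GroundTruth", states = as.character(ep$state), params = params,
    dropouts = dr, epochS = raw$epochS, fs = raw$fs)
}
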