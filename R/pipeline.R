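#' @include AllClasses.R preprocess.R correlation.R decay.R staging.R state-analysis.R threshold.R io.R
NULL

.CONFIG_KEYS <- c("epochS", "binWidthUm", "cutoffHz", "filterOrder",
  "fsOut", "bands", "models", "excludeLowCountFrac", "nTapers",
  "clusterer", "nBoot", "seed", "thresholdParam", "nShuffles")

#' Pipeline configuration
#'
#' All stage parameters of [runPipeline()] with their defaults. The
#' configuration is serializable to and from JSON; unknown keys are
#' rejected.
#'
#' @param epochS epoch duration in seconds.
#' @param binWidthUm distance bin width in um.
#' @param cutoffHz,filterOrder,fsOut LFP extraction parameters (only used
#'   when raw high-rate input is supplied).
#' @param bands staging band edges in Hz.
#' @param models decay models to fit (first one drives the state
#'   analysis).
#' @param excludeLowCountFrac optional low-count bin exclusion fraction.
#' @param nTapers multitaper taper count.
#' @param clusterer staging clusterer (only \code{"gmm"} is implemented).
#' @param nBoot bootstrap resamples for confidence intervals.
#' @param seed integer seed for all stochastic stages.
#' @param thresholdParam parameter thresholded by the simple SWS
#'   classifier (\code{"param_ratio"}, \code{"A"} or \code{"lambda_um"}).
#' @param nShuffles label shuffles for the classifier null.
#' @return named list of validated parameters.
#' @export
pipelineConfig <- function(epochS = 10, binWidthUm = 600, cutoffHz = 250,
    filterOrder = 3L, fsOut = 1000,
    bands = list(delta = c(0.1, 4), gamma = c(30, 60)),
    models = c("exponential", "linear"), excludeLowCountFrac = NULL,
    nTapers = 5L, clusterer = "gmm", nBoot = 1000L, seed = 7L,
    thresholdParam = "param_ratio", nShuffles = 1000L) {
  cfg <- list(epochS = epochS, binWidthUm = binWidthUm, cutoffHz = cutoffHz,
    filterOrder = filterOrder, fsOut = fsOut, bands = bands,
    models = models, excludeLowCountFrac = excludeLowCountFrac,
    nTapers = nTapers, clusterer = clusterer, nBoot = nBoot, seed = seed,
    thresholdParam = thresholdParam, nShuffles = nShuffles)
  stopifnot(cfg$epochS > 0, cfg$binWidthUm > 0,
    cfg$clusterer == "gmm",
    cfg$thresholdParam %in% c("param_ratio", "A", "lambda_um"))
  cfg
}

#' @rdname pipelineConfig
#' @param path JSON file path.
#' @param config a configuration list.
#' @export
writeConfig <- function(config, path) {
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
    null = "null"), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  raw$bands <- lapply(raw$bands, unlist)
  do.call(pipelineConfig, raw)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes preprocess (z-scoring, epoch grid) -> spatial correlation ->
#' decay model fits -> sleep staging -> state analysis on each session,
#' and -- when two or more sessions are supplied -- the leave-one-out
#' threshold SWS classifier with its shuffle null. Every output carries
#' the configuration hash and seed for provenance, and a structured log of
#' per-stage exclusion counts.
#'
#' @param recordings a [Recording-class] or list of them (one per
#'   session).
#' @param layout the common [ArrayLayout-class].
#' @param config a [pipelineConfig()] list.
#' @return list with \code{sessions} (per-session tables: fits, states,
#'   merged epochs, correlation result, summaries), \code{classifier}
#'   (NULL for a single session), and \code{provenance}.
#' @export
runPipeline <- function(recordings, layout, config = pipelineConfig()) {
  if (is(recordings, "Recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L)
  runSession <- function(rec, sessionIndex) {
    if (!rec@zscored) rec <- zscoreChannels(rec)
    grid <- buildEpochGrid(rec, config$epochS)
    log <- list(invalidEpochs = sum(!validEpochs(grid)),
      excludedChannels = length(excludedChannels(rec)))
    fn <- distanceCorrelations(rec, layout, grid, config$binWidthUm)
    fits <- fitDecayModels(fn, models = config$models,
      excludeLowCountFrac = config$excludeLowCountFrac)
    primary <- fits[fits$model == config$models[1L], , drop = FALSE]
    log$failedFits <- sum(!primary$ok)
    states <- stageSleep(rec, grid, bands = config$bands,
      nTapers = config$nTapers, seed = config$seed)
    merged <- joinEpochs(primary, states)
    log$joinExcluded <- attr(merged, "excluded")
    summary <- stateParameterSummary(merged, nBoot = config$nBoot,
      seed = config$seed)
    ratios <- correlateRatios(merged$param_ratio, merged$power_ratio,
      nBoot = config$nBoot, seed = config$seed)
    paramScatter <- type2Regression(merged$A, merged$lambda_um,
      nBoot = config$nBoot, seed = config$seed)
    dp <- if (all(c("SWS", "REM_AWAKE") %in% merged$state) &&
        min(table(merged$state)[c("SWS", "REM_AWAKE")]) >= 2L)
      dprime(merged$param_ratio[merged$state == "SWS"],
        merged$param_ratio[merged$state == "REM_AWAKE"])
    else NA_real_
    list(session = sessionIndex, correlation = fn, fits = fits,
      states = states, merged = merged, summary = summary,
      ratioCorrelation = ratios, parameterScatter = paramScatter,
      dprimeSwsRem = dp, log = log)
  }
  sessions <- lapply(seq_along(recordings), function(i)
    runSession(recordings[[i]], i))
  classifier <- NULL
  if (length(sessions) >= 2L) {
    inputs <- lapply(sessions, function(s) list(
      values = s$merged[[config$thresholdParam]],
      sws = s$merged$state == "SWS"))
    folds <- trainThresholdLOO(inputs)
    classifier <- lapply(seq_along(folds), function(i) {
      nullDist <- shuffleNull(inputs[[i]]$values, inputs[[i]]$sws,
        folds[[i]]$model, nShuffles = config$nShuffles,
        seed = config$seed + i)
      perf <- accuracyPrecision(folds[[i]]$predictions, inputs[[i]]$sws)
      c(folds[[i]][c("model", "trainError", "testError")],
        list(null = nullDist, performance = perf))
    })
  }
  list(sessions = sessions, classifier = classifier,
    provenance = list(configHash = .configHash(config),
      seed = config$seed, config = config,
      timestamp = format(Sys.time(), tz = "UTC")))
}

#' Characterize wireless signal dropouts
#'
#' Tables of dropout durations, dropouts per epoch, and the quiet
#' intervals between consecutive dropouts, with their means; derived from
#' the recording's validity mask.
#'
#' @param rec a [Recording-class].
#' @param epochS epoch duration for the per-epoch counts (default 10 s).
#' @return list with data.frames \code{durations} (seconds),
#'   \code{perEpoch} (epoch, count; all epochs listed), \code{intervals}
#'   (seconds between the end of one dropout and the start of the next),
#'   and a \code{means} list.
#' @export
dropoutReport <- function(rec, epochS = 10) {
  iv <- maskIntervals(rec)
  totalS <- nSamples(rec) / samplingRate(rec)
  nEp <- floor(totalS / epochS)
  perEpoch <- data.frame(epoch = seq_len(nEp), count = 0L)
  if (nrow(iv)) {
    ep <- pmin(floor(iv$start_s / epochS) + 1L, nEp)
    tab <- table(factor(ep, levels = seq_len(nEp)))
    perEpoch$count <- as.integer(tab)
  }
  durations <- data.frame(duration_s = iv$end_s - iv$start_s)
  gaps <- if (nrow(iv) > 1L)
    iv$start_s[-1L] - iv$end_s[-nrow(iv)] else numeric()
  list(durations = durations, perEpoch = perEpoch,
    intervals = data.frame(interval_s = gaps),
    means = list(
      duration_s = if (nrow(durations)) mean(durations$duration_s) else NA_real_,
      perEpoch = mean(perEpoch$count),
      interval_s = if (length(gaps)) mean(gaps) else NA_real_))
}
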