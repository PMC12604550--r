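#' @include AllClasses.R AllGenerics.R filters.R layout.R recording-methods.R
NULL

#' Generator parameterization for synthetic LFP sessions
#'
#' Each channel is a sum over frequency-band components (SO/delta 0.1-4 Hz
#' and gamma 30-60 Hz by default). Within a band, channel \eqn{i} receives
#' \deqn{x_i(t) = \sigma_g g(t) + \sigma_s s_i(t) + \sigma_n n_i(t),}
#' where \eqn{g} is a band-limited signal shared by all channels, \eqn{s_i}
#' is a band-limited spatial field with inter-channel correlation
#' \eqn{e^{-d_{ij}/\ell}}, and \eqn{n_i} is independent channel noise. The
#' expected inter-channel correlation is then
#' \eqn{\rho^*(d) = \sum_b(\sigma_g^2 + \sigma_s^2 e^{-d/\ell}) /
#' \sum_b(\sigma_g^2+\sigma_s^2+\sigma_n^2)}: a distance-decaying profile
#' over a nonzero plateau, the structure this package's estimators target.
#'
#' Default amplitudes put slow-wave-sleep epochs in a delta-dominated,
#' high-correlation regime (pooled Pearson correlation around 0.8 at 600 um
#' falling toward 0.5 at 4200 um) and REM/awake epochs in a gamma-dominated,
#' flatter and weaker regime; the NULL state is an amplitude mixture midway
#' between the two.
#'
#' @param fs sampling rate in Hz (default 250; the synthetic content is
#'   band-limited below 60 Hz).
#' @param epochS epoch duration in seconds (default 10).
#' @param bands named list of band edges in Hz.
#' @param states named list (one entry per state in [SLEEP_STATES]) with
#'   elements \code{ellUm} (generative spatial length constant, um),
#'   \code{ellJitterSd} (sdlog of the per-epoch lognormal jitter applied
#'   to \code{ellUm}; models within-state heterogeneity, larger in
#'   REM/awake than in SWS) and \code{amp}: per band a named numeric
#'   vector \code{c(global=, spatial=, local=)} of component amplitudes.
#' @param transition 3 x 3 row-stochastic state transition matrix
#'   (rows/columns ordered as [SLEEP_STATES]).
#' @param dropoutRateHz mean dropout rate in Hz.
#' @param dropoutMedianS median dropout duration (log-normal), seconds.
#' @param dropoutSdlog log-normal sdlog of dropout durations.
#' @param burstiness fraction of inter-dropout gaps drawn from the short
#'   "burst" gap distribution (dropouts cluster in time).
#' @param burstGapS mean of the short burst gap, seconds.
#'
#' @return a validated list of generator parameters.
#' @examples
#' p <- generatorParams()
#' round(expectedCorrelation(p, "SWS", c(600, 4200)), 2)
#' @export
generatorParams <- function(fs = 250, epochS = 10,
    bands = list(delta = c(0.1, 4), gamma = c(30, 60)),
    states = NULL, transition = NULL,
    dropoutRateHz = 0.02, dropoutMedianS = 0.3, dropoutSdlog = 1,
    burstiness = 0.5, burstGapS = 2) {
  if (is.null(states)) {
    sws <- list(ellUm = 3000, ellJitterSd = 0.10, amp = list(
      delta = c(global = 0.550, spatial = 0.822, local = 0.148),
      gamma = c(global = 0.224, spatial = 0.316, local = 0.224)))
    rem <- list(ellUm = 4000, ellJitterSd = 0.45, amp = list(
      delta = c(global = 0.141, spatial = 0.173, local = 0.100),
      gamma = c(global = 0.560, spatial = 0.684, local = 0.467)))
    mid <- function(a, b) Map(function(u, v) (u + v) / 2, a, b)
    states <- list(
      SWS = sws,
      REM_AWAKE = rem,
      `NULL` = list(ellUm = 3500, ellJitterSd = 0.30,
        amp = mid(sws$amp, rem$amp)))
  }
  if (is.null(transition)) {
    transition <- matrix(c(
      0.92, 0.02, 0.06,
      0.02, 0.92, 0.06,
      0.30, 0.30, 0.40), 3, 3, byrow = TRUE,
      dimnames = list(SLEEP_STATES, SLEEP_STATES))
  }
  p <- list(fs = fs, epochS = epochS, bands = bands, states = states,
    transition = transition, dropoutRateHz = dropoutRateHz,
    dropoutMedianS = dropoutMedianS, dropoutSdlog = dropoutSdlog,
    burstiness = burstiness, burstGapS = burstGapS)
  .validateGeneratorParams(p)
  p
}

.validateGeneratorParams <- function(p) {
  stopifnot(p$fs > 0, p$epochS > 0)
  .checkTransition(p$transition)
  if (!setequal(names(p$states), SLEEP_STATES))
    stop("states must be parameterized for exactly ", paste(SLEEP_STATES, collapse = ", "))
  for (s in names(p$states)) {
    st <- p$states[[s]]
    if (st$ellUm <= 0) stop("ellUm must be positive")
    if (!is.null(st$ellJitterSd) && st$ellJitterSd < 0)
      stop("ellJitterSd must be non-negative")
    if (!setequal(names(st$amp), names(p$bands)))
      stop("state '", s, "' must carry one amplitude set per band")
    for (b in names(st$amp)) {
      a <- st$amp[[b]]
      if (!all(c("global", "spatial", "local") %in% names(a)))
        stop("amplitudes must be named global/spatial/local")
      if (any(a < 0)) stop("amplitudes must be non-negative")
    }
  }
  # SWS must be delta-dominated and REM_AWAKE gamma-dominated (by per-Hz
  # band power density)
  dens <- function(state, band) {
    sum(p$states[[state]]$amp[[band]]^2) / diff(p$bands[[band]])
  }
  if (dens("SWS", "delta") <= dens("SWS", "gamma"))
    stop("SWS parameterization must be delta-dominated")
  if (dens("REM_AWAKE", "gamma") <= dens("REM_AWAKE", "delta"))
    stop("REM_AWAKE parameterization must be gamma-dominated")
  invisible(TRUE)
}

.checkTransition <- function(P) {
  if (!is.matrix(P) || !identical(dim(P), c(3L, 3L)))
    stop("transition must be a 3 x 3 matrix")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  invisible(TRUE)
}

#' @rdname expectedCorrelation
#' @export
setMethod("expectedCorrelation", "list", function(x, state, d) {
  st <- x$states[[state]]
  if (is.null(st)) stop("unknown state: ", state)
  num <- 0
  den <- 0
  for (b in names(st$amp)) {
    a <- st$amp[[b]]
    num <- num + a[["global"]]^2 + a[["spatial"]]^2 * exp(-d / st$ellUm)
    den <- den + sum(a^2)
  }
  num / den
})

#' @rdname expectedCorrelation
#' @export
setMethod("expectedCorrelation", "GroundTruth", function(x, state, d) {
  expectedCorrelation(x@params, state, d)
})

#' Simulate a Markov sequence of sleep states
#'
#' @param nEpochs number of epochs (>= 1).
#' @param transition 3 x 3 row-stochastic matrix over [SLEEP_STATES].
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @param init initial state label, or \code{"stationary"} to draw the
#'   first state from the stationary distribution of \code{transition}
#'   (falls back to uniform if the chain has no unique stationary law).
#' @return character vector of state labels.
#' @examples
#' generateStateSequence(10, diag(3), seed = 1, init = "SWS")
#' @export
generateStateSequence <- function(nEpochs, transition, seed = NULL,
                                  init = "stationary") {
  stopifnot(nEpochs >= 1)
  .checkTransition(transition)
  if (!is.null(seed)) set.seed(seed)
  if (identical(init, "stationary")) {
    pi0 <- .stationaryDistribution(transition)
    s <- sample(SLEEP_STATES, 1L, prob = pi0)
  } else {
    if (!init %in% SLEEP_STATES) stop("unknown initial state: ", init)
    s <- init
  }
  out <- character(nEpochs)
  out[1L] <- s
  idx <- match(s, SLEEP_STATES)
  if (nEpochs > 1L) for (k in 2L:nEpochs) {
    idx <- sample.int(3L, 1L, prob = transition[idx, ])
    out[k] <- SLEEP_STATES[idx]
  }
  out
}

.stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(abs(v)) < 1e-12 || abs(Re(e$values[i]) - 1) > 1e-8)
    return(rep(1 / 3, 3))
  v <- abs(v)
  # non-unique stationary law (e.g. identity chain): fall back to uniform
  if (sum(abs(e$values - 1) < 1e-8) > 1L) return(rep(1 / 3, 3))
  v / sum(v)
}

#' Generate one synthetic multichannel LFP epoch
#'
#' See [generatorParams()] for the generative model. The spatial field is
#' realized by applying the Cholesky factor of the target covariance
#' \eqn{C_{ij} = e^{-d_{ij}/\ell}} (with diagonal jitter if needed) to
#' independent channel noise; the spatial length constant is jittered per
#' epoch when the state's \code{ellJitterSd} is positive. All components
#' are band-limited by applying the zero-phase 4th-order Butterworth
#' magnitude response exactly at the epoch's DFT frequencies and
#' normalized to unit variance per component, so the amplitude parameters
#' are in z-units.
#'
#' @param layout an [ArrayLayout-class].
#' @param state state label in [SLEEP_STATES].
#' @param params a [generatorParams()] list.
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @param cholCache optional environment for caching Cholesky factors
#'   across epochs (used by [generateSession()]).
#' @return channels x samples numeric matrix.
#' @export
generateEpoch <- function(layout, state, params, seed = NULL,
                          cholCache = NULL) {
  stopifnot(is(layout, "ArrayLayout"))
  if (!state %in% SLEEP_STATES) stop("unknown state: ", state)
  if (!is.null(seed)) set.seed(seed)
  st <- params$states[[state]]
  nc <- nChannels(layout)
  n <- round(params$epochS * params$fs)
  jit <- if (is.null(st$ellJitterSd)) 0 else st$ellJitterSd
  ellEff <- if (jit > 0) st$ellUm * stats::rlnorm(1, 0, jit) else st$ellUm
  L <- .spatialCholesky(layout, ellEff, cholCache)
  out <- matrix(0, nc, n)
  for (b in names(params$bands)) {
    a <- st$amp[[b]]
    band <- params$bands[[b]]
    if (a[["global"]] > 0) {
      g <- .fftUnitBandNoise(stats::rnorm(n), params$fs, band)
      out <- out + a[["global"]] * matrix(g, nc, n, byrow = TRUE)
    }
    if (a[["spatial"]] > 0) {
      E <- .fftUnitBandNoise(matrix(stats::rnorm(nc * n), nc, n),
        params$fs, band)
      out <- out + a[["spatial"]] * (L %*% E)
    }
    if (a[["local"]] > 0) {
      out <- out + a[["local"]] *
        .fftUnitBandNoise(matrix(stats::rnorm(nc * n), nc, n),
          params$fs, band)
    }
  }
  dimnames(out) <- list(channelIds(layout), NULL)
  out
}

# Lower-triangular factor L with L %*% t(L) = exp(-D/ell) (+ jitter).
.spatialCholesky <- function(layout, ellUm, cache = NULL) {
  key <- sprintf("ell%.6g", ellUm)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  C <- exp(-electrodeDistances(layout) / ellUm)
  L <- NULL
  jitter <- 0
  for (j in c(0, 1e-9, 1e-7, 1e-5)) {
    Cj <- C + diag(j, nrow(C))
    L <- tryCatch(t(chol(Cj)), error = function(e) NULL)
    jitter <- j
    if (!is.null(L)) break
  }
  if (is.null(L))
    stop("spatial covariance is not positive definite even after jitter")
  if (!is.null(cache)) cache[[key]] <- L
  L
}

#' Generate a full synthetic session
#'
#' Simulates a state sequence, generates each epoch under its state's
#' parameterization, concatenates the epochs, and injects wireless-dropout
#' artifacts. Fully reproducible for a fixed seed.
#'
#' @param layout an [ArrayLayout-class].
#' @param params a [generatorParams()] list.
#' @param nEpochs number of epochs (0 gives an empty session).
#' @param seed integer seed for the whole session.
#' @param init initial state, passed to [generateStateSequence()].
#' @param dropouts logical; inject dropouts (default TRUE)?
#' @return list with elements \code{recording} (a [Recording-class]) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' sess <- generateSession(utahArrayLayout(), generatorParams(),
#'   nEpochs = 2, seed = 1)
#' sess$recording
#' @export
generateSession <- function(layout, params, nEpochs, seed = NULL,
                            init = "stationary", dropouts = TRUE) {
  .validateGeneratorParams(params)
  if (!is.null(seed)) set.seed(seed)
  nc <- nChannels(layout)
  n <- round(params$epochS * params$fs)
  if (nEpochs == 0L) {
    rec <- newRecording(matrix(0, nc, 0), params$fs,
      channelIds = channelIds(layout))
    truth <- new("GroundTruth", states = character(), params = params,
      dropouts = data.frame(start_s = numeric(), end_s = numeric()),
      epochS = params$epochS, fs = params$fs)
    return(list(recording = rec, truth = truth))
  }
  states <- generateStateSequence(nEpochs, params$transition, init = init)
  cache <- new.env(parent = emptyenv())
  sig <- matrix(0, nc, n * nEpochs)
  for (k in seq_len(nEpochs)) {
    sig[, ((k - 1L) * n + 1L):(k * n)] <-
      generateEpoch(layout, states[k], params, cholCache = cache)
  }
  rec <- newRecording(sig, params$fs, channelIds = channelIds(layout))
  if (dropouts && params$dropoutRateHz > 0) {
    rec <- injectDropouts(rec, rateHz = params$dropoutRateHz,
      durMedianS = params$dropoutMedianS, durSdlog = params$dropoutSdlog,
      burstiness = params$burstiness, burstGapS = params$burstGapS)
  }
  truth <- new("GroundTruth", states = states, params = params,
    dropouts = maskIntervals(rec), epochS = params$epochS, fs = params$fs)
  list(recording = rec, truth = truth)
}

#' Inject wireless-dropout artifacts
#'
#' Marks dropout intervals invalid in the recording's validity mask and
#' sets all channels to a constant over them. Interval onsets follow a
#' renewal process whose gaps are a mixture of a short "burst" exponential
#' (with probability \code{burstiness}) and a longer exponential chosen so
#' the overall rate is \code{rateHz}; durations are log-normal with the
#' given median (multi-second tails allowed).
#'
#' @param rec a [Recording-class].
#' @param rateHz mean dropout rate (>= 0; 0 is a no-op).
#' @param durMedianS median dropout duration in seconds.
#' @param durSdlog log-normal sdlog of durations.
#' @param burstiness probability of a short burst gap (0 gives a pure
#'   Poisson process of onsets).
#' @param burstGapS mean short gap in seconds.
#' @param intervals optional data.frame with columns \code{start_s},
#'   \code{end_s}: inject exactly these intervals instead of sampling.
#' @param fillValue constant value written over dropout samples.
#' @param seed optional integer seed.
#' @return the recording with updated signal and validity mask.
#' @export
injectDropouts <- function(rec, rateHz, durMedianS = 0.3, durSdlog = 1,
                           burstiness = 0, burstGapS = 2, intervals = NULL,
                           fillValue = 0, seed = NULL) {
  stopifnot(is(rec, "Recording"))
  if (is.null(intervals)) {
    if (rateHz < 0) stop("dropout rate must be non-negative")
    if (!is.null(seed)) set.seed(seed)
    totalS <- nSamples(rec) / samplingRate(rec)
    if (rateHz == 0 || totalS == 0) return(rec)
    meanGap <- 1 / rateHz
    longGap <- (meanGap - burstiness * burstGapS) / max(1 - burstiness, 1e-12)
    if (longGap <= 0) stop("burstiness/burstGapS incompatible with rateHz")
    starts <- numeric()
    t <- 0
    repeat {
      gap <- if (stats::runif(1) < burstiness) stats::rexp(1, 1 / burstGapS)
        else stats::rexp(1, 1 / longGap)
      t <- t + gap
      if (t >= totalS) break
      starts <- c(starts, t)
    }
    if (!length(starts)) return(rec)
    durs <- stats::rlnorm(length(starts), meanlog = log(durMedianS),
      sdlog = durSdlog)
    intervals <- data.frame(start_s = starts,
      end_s = pmin(starts + durs, totalS))
  }
  fs <- samplingRate(rec)
  sig <- rec@signal
  valid <- rec@valid
  for (i in seq_len(nrow(intervals))) {
    # samples covering [start, end): sample k spans [(k-1)/fs, k/fs)
    from <- floor(intervals$start_s[i] * fs) + 1L
    to <- ceiling(intervals$end_s[i] * fs)
    from <- max(1L, from)
    to <- min(nSamples(rec), to)
    if (from > to) next
    sig[, from:to] <- fillValue
    valid[from:to] <- FALSE
  }
  initialize(rec, signal = sig, valid = valid)
}

#' Invalid-sample intervals of a recording
#'
#' Derives the contiguous invalid (dropout/artifact) intervals from a
#' recording's validity mask.
#'
#' @param rec a [Recording-class].
#' @return data.frame with columns \code{start_s}, \code{end_s} (end
#'   exclusive).
#' @export
maskIntervals <- function(rec) {
  stopifnot(is(rec, "Recording"))
  bad <- !validMask(rec)
  if (!any(bad))
    return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  fs <- samplingRate(rec)
  data.frame(start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}
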