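#' @include AllClasses.R AllGenerics.R preprocess.R
NULL

# Orthonormal sine tapers (Riedel & Sidorenko): closed-form multitaper
# family; taper k over N samples is sqrt(2/(N+1)) sin(pi k t / (N+1)).
.sineTapers <- function(n, k) {
  t <- seq_len(n)
  vapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)),
    numeric(n))
}

# One-sided multitaper PSD. With unit-norm tapers the estimate satisfies
# Parseval: sum(psd) * fs / n ~ var(x).
.multitaperPSD <- function(x, fs, nTapers = 5L) {
  n <- length(x)
  tap <- .sineTapers(n, nTapers)
  spec <- Mod(stats::mvfft(tap * x))^2
  half <- seq(2L, floor(n / 2) + 1L)  # exclude DC
  psd <- 2 / (fs * nTapers) * rowSums(spec)[half]
  list(freq = (half - 1L) * fs / n, psd = psd)
}

#' Multitaper band power per epoch
#'
#' Estimates the power spectrum of a single-channel series (typically the
#' virtual LFP) within each valid epoch using a sine-taper multitaper
#' estimator (default 5 tapers), and averages the spectral estimates at
#' frequencies inside each band (inclusive edges).
#'
#' @param x numeric series (e.g. from [makeVirtualLFP()]).
#' @param grid an [EpochGrid-class] for the series.
#' @param bands named list of band edges in Hz (default SO/delta 0.1-4 and
#'   gamma 30-60).
#' @param nTapers number of sine tapers (default 5).
#' @param fs sampling rate in Hz (defaults to the grid's rate).
#' @return data.frame with one row per valid epoch: \code{epoch},
#'   \code{t_start_s}, and one \code{<band>_power} column per band
#'   (mean spectral power, signal-units^2/Hz).
#' @export
multitaperBandPower <- function(x, grid, bands = list(delta = c(0.1, 4),
    gamma = c(30, 60)), nTapers = 5L, fs = NULL) {
  stopifnot(is(grid, "EpochGrid"))
  if (is.null(fs)) fs <- grid@fs
  n <- grid@epochLength
  df <- fs / n
  freq <- seq_len(floor(n / 2)) * df
  bandBins <- lapply(bands, function(e) {
    if (e[2] >= fs / 2) stop("band upper edge must be below Nyquist")
    sel <- which(freq >= e[1] - 1e-9 & freq <= e[2] + 1e-9)
    if (!length(sel))
      stop("no resolvable frequency bins in band [", e[1], ", ", e[2],
        "] Hz at epoch length ", grid@epochS, " s")
    sel
  })
  epochs <- which(grid@valid)
  out <- data.frame(epoch = epochs,
    t_start_s = (grid@starts[epochs] - 1L) / fs)
  pw <- matrix(NA_real_, length(epochs), length(bands))
  for (i in seq_along(epochs)) {
    seg <- x[grid@starts[epochs[i]]:(grid@starts[epochs[i]] + n - 1L)]
    psd <- .multitaperPSD(seg, fs, nTapers)$psd
    pw[i, ] <- vapply(bandBins, function(sel) mean(psd[sel]), numeric(1))
  }
  colnames(pw) <- paste0(names(bands), "_power")
  cbind(out, as.data.frame(pw))
}

#' Gaussian-mixture clustering of epoch features
#'
#' Fits a full-covariance Gaussian mixture with \code{k} components to the
#' feature matrix (standardized log10 band powers in the staging pipeline)
#' and assigns each epoch to its maximum-posterior component. The
#' underlying EM uses a deterministic model-based hierarchical
#' initialization, so results are reproducible; \code{seed} is accepted
#' for interface stability.
#'
#' @param features numeric matrix, epochs x features (>= k rows, nonzero
#'   variance per column).
#' @param k number of components (default 3).
#' @param seed optional integer seed.
#' @return list with \code{cluster} (integer assignments), \code{means}
#'   (k x features matrix of component means), \code{posterior}
#'   (epochs x k matrix).
#' @importFrom mclust Mclust mclustBIC
#' @export
clusterStates <- function(features, k = 3L, seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < k) stop("need at least k epochs to cluster")
  if (any(apply(features, 2L, stats::sd) == 0))
    stop("degenerate features: zero variance column")
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    return(list(cluster = rep(1L, nrow(features)),
      means = matrix(colMeans(features), 1L,
        dimnames = list(NULL, colnames(features))),
      posterior = matrix(1, nrow(features), 1L)))
  }
  fit <- mclust::Mclust(features, G = k, modelNames = "VVV",
    verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed")
  list(cluster = as.integer(fit$classification),
    means = t(fit$parameters$mean), posterior = fit$z)
}

#' Map clusters to sleep states
#'
#' Ranks clusters by mean standardized delta minus gamma power: the
#' maximizing cluster is SWS (delta-dominated), the minimizing one
#' REM/awake (gamma-dominated), the remaining one NULL. Ties are broken
#' deterministically by cluster index, with a warning.
#'
#' @param clusterMeans k x 2 matrix of cluster means with columns ordered
#'   (delta, gamma) in standardized feature units.
#' @return character vector of length k: state label per cluster.
#' @examples
#' labelClusters(rbind(c(2, -2), c(-2, 2), c(0, 0)))
#' @export
labelClusters <- function(clusterMeans) {
  clusterMeans <- as.matrix(clusterMeans)
  if (nrow(clusterMeans) != 3L || ncol(clusterMeans) < 2L)
    stop("need 3 clusters with (delta, gamma) mean features")
  score <- clusterMeans[, 1L] - clusterMeans[, 2L]
  if (anyDuplicated(score))
    warning("tie in cluster ranking; broken by cluster index")
  states <- rep("NULL", 3L)
  states[which.max(score)] <- "SWS"
  # which.min on the remaining clusters so a global tie cannot collapse
  rem <- setdiff(seq_len(3L), which.max(score))
  states[rem[which.min(score[rem])]] <- "REM_AWAKE"
  states
}

#' Stage every epoch from virtual-LFP band power
#'
#' The full staging pipeline: virtual LFP, multitaper SO/delta and gamma
#' band power per valid epoch, Gaussian-mixture clustering of the
#' standardized log10 band powers, and cluster-to-state mapping.
#'
#' @param rec a z-scored [Recording-class].
#' @param grid an [EpochGrid-class].
#' @param bands named list of the two staging bands, in order
#'   (delta-like, gamma-like).
#' @param nTapers number of sine tapers for the spectral estimate.
#' @param seed optional integer seed (see [clusterStates()]).
#' @return data.frame with one row per valid epoch: \code{epoch},
#'   \code{t_start_s}, \code{delta_power}, \code{gamma_power},
#'   \code{cluster}, \code{state}, \code{posterior_max}.
#' @export
stageSleep <- function(rec, grid, bands = list(delta = c(0.1, 4),
    gamma = c(30, 60)), nTapers = 5L, seed = NULL) {
  vlfp <- makeVirtualLFP(rec)
  bp <- multitaperBandPower(vlfp, grid, bands, nTapers)
  pcols <- paste0(names(bands), "_power")
  if (any(as.matrix(bp[pcols]) <= 0))
    stop("band powers must be positive for the log transform")
  features <- scale(log10(as.matrix(bp[pcols])))
  cl <- clusterStates(features, k = 3L, seed = seed)
  stateOf <- labelClusters(cl$means)
  out <- bp
  names(out)[match(pcols, names(out))] <- c("delta_power", "gamma_power")
  out$cluster <- cl$cluster
  out$state <- stateOf[cl$cluster]
  out$posterior_max <- apply(cl$posterior, 1L, max)
  out
}
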