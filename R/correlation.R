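#' @include AllClasses.R AllGenerics.R layout.R preprocess.R
NULL

#' Fisher z-transform and its inverse
#'
#' \code{fisherZ} maps a Pearson correlation to \code{atanh(r)}, the
#' variance-stabilizing transform used before averaging and regressing
#' correlations; \code{inverseFisherZ} maps back with \code{tanh}.
#' Pathological values with \code{|r| >= 1} (duplicate or railed channels)
#' are clipped to \code{1 - clipTol} in magnitude, with a warning reporting
#' how many values were clipped.
#'
#' @param r correlations.
#' @param z Fisher z values.
#' @param clipTol clip margin for |r| >= 1 (default 1e-7).
#' @return transformed values.
#' @examples
#' fisherZ(0.5)            # 0.5493
#' inverseFisherZ(fisherZ(0.3))
#' @export
fisherZ <- function(r, clipTol = 1e-7) {
  nClip <- sum(abs(r) >= 1, na.rm = TRUE)
  if (nClip > 0) {
    warning(nClip, " correlation value(s) with |r| >= 1 clipped before atanh")
    r <- pmin(pmax(r, -(1 - clipTol)), 1 - clipTol)
  }
  atanh(r)
}

#' @rdname fisherZ
#' @export
inverseFisherZ <- function(z) tanh(z)

#' Half-open distance bin edges
#'
#' Bins partition \code{(0, dMax]} into half-open intervals
#' \code{(lower, upper]} of fixed width; the upper edge is the nominal
#' distance of the bin (a 600 um first bin is labelled 600).
#'
#' @param dMax largest distance to cover (um).
#' @param widthUm bin width (default 600; 400 is the common alternative).
#' @return numeric vector of bin upper edges.
#' @export
distanceBinEdges <- function(dMax, widthUm = 600) {
  seq_len(ceiling(dMax / widthUm)) * widthUm
}

# Bin index per pairwise distance: interval (edges[i-1], edges[i]].
.binIndex <- function(d, upper) {
  out <- findInterval(d, c(0, upper), left.open = TRUE)
  if (!is.null(dim(d))) dim(out) <- dim(d)
  out
}

#' Pearson correlation matrix of one epoch
#'
#' Pairwise Pearson correlations between all non-excluded channels over the
#' samples of a single valid epoch. The Pearson formula re-centers
#' internally, so per-session z-scoring upstream does not change the
#' result.
#'
#' @param rec a [Recording-class].
#' @param grid an [EpochGrid-class] for the recording.
#' @param epoch epoch index (must be a valid epoch).
#' @return symmetric correlation matrix over non-excluded channels.
#' @export
epochCorrelationMatrix <- function(rec, grid, epoch) {
  stopifnot(is(rec, "Recording"), is(grid, "EpochGrid"))
  if (epoch < 1L || epoch > nEpochs(grid)) stop("epoch index out of range")
  if (!grid@valid[epoch])
    stop("epoch ", epoch, " is invalid (overlaps artifact samples)")
  keep <- .keptChannels(rec)
  cols <- grid@starts[epoch]:(grid@starts[epoch] + grid@epochLength - 1L)
  C <- stats::cor(t(rec@signal[keep, cols, drop = FALSE]))
  dimnames(C) <- list(rec@channelIds[keep], rec@channelIds[keep])
  C
}

#' Per-source distance binning of a correlation matrix
#'
#' For each source electrode, Fisher z-transforms its row of pairwise
#' correlations and averages the values within half-open distance bins;
#' records the number of pair observations per source per bin. Empty bins
#' carry count 0 and an NA mean.
#'
#' @param corrMat square correlation matrix.
#' @param distances matching pairwise distance matrix (um).
#' @param binUpperUm bin upper edges (um), e.g. [distanceBinEdges()].
#' @return list with matrices \code{z} (sources x bins, mean Fisher z) and
#'   \code{counts}.
#' @export
binByDistance <- function(corrMat, distances, binUpperUm) {
  if (!identical(dim(corrMat), dim(distances)))
    stop("correlation and distance matrices must share the channel set")
  n <- nrow(corrMat)
  diag(corrMat) <- 0  # self-pairs are never binned; avoid atanh(1) clipping
  z <- fisherZ(corrMat)
  bi <- .binIndex(distances, binUpperUm)
  bi[cbind(seq_len(n), seq_len(n))] <- 0L
  nb <- length(binUpperUm)
  sums <- matrix(0, n, nb)
  counts <- matrix(0L, n, nb)
  for (b in seq_len(nb)) {
    m <- bi == b
    sums[, b] <- rowSums(z * m)
    counts[, b] <- rowSums(m)
  }
  means <- sums / counts
  means[counts == 0L] <- NA_real_
  list(z = means, counts = counts)
}

#' Count-weighted array average of per-source functions
#'
#' Pools per-source binned functions into one array-level correlation by
#' distance function, weighting each source's bin mean by its number of
#' pair observations. Bins empty on every source are marked missing.
#'
#' @param binned result of [binByDistance()].
#' @return list with vectors \code{z} (weighted mean Fisher z per bin) and
#'   \code{counts} (total observations per bin).
#' @export
arrayAverage <- function(binned) {
  counts <- colSums(binned$counts)
  num <- colSums(ifelse(binned$counts > 0L, binned$z * binned$counts, 0))
  z <- num / counts
  z[counts == 0L] <- NA_real_
  list(z = z, counts = as.integer(counts))
}

#' Correlation-by-distance functions for every valid epoch
#'
#' The full spatial-correlation pipeline: per valid epoch, the Pearson
#' correlation matrix of all non-excluded channels is Fisher z-transformed,
#' binned by inter-electrode distance per source electrode, and pooled
#' across sources by count weighting.
#'
#' @param rec a [Recording-class] whose channels match \code{layout}.
#' @param layout the [ArrayLayout-class] of the recording.
#' @param grid an [EpochGrid-class]; only valid epochs are processed.
#' @param binWidthUm distance bin width in um (default 600).
#' @param band label stored on the result (default \code{"broadband"}).
#' @return a [DistanceCorrelation-class] with one row per valid epoch.
#' @export
distanceCorrelations <- function(rec, layout, grid, binWidthUm = 600,
                                 band = "broadband") {
  stopifnot(is(rec, "Recording"), is(layout, "ArrayLayout"),
    is(grid, "EpochGrid"))
  if (!identical(channelIds(rec), channelIds(layout)))
    stop("recording and layout channel ids must match")
  keep <- .keptChannels(rec)
  if (length(keep) < 2L) stop("need at least two non-excluded channels")
  D <- electrodeDistances(layout)[keep, keep, drop = FALSE]
  edges <- distanceBinEdges(max(D), binWidthUm)
  epochs <- which(grid@valid)
  if (!length(epochs)) stop("no valid epochs")
  zMat <- matrix(NA_real_, length(epochs), length(edges))
  cMat <- matrix(0L, length(epochs), length(edges))
  for (i in seq_along(epochs)) {
    C <- epochCorrelationMatrix(rec, grid, epochs[i])
    pooled <- arrayAverage(binByDistance(C, D, edges))
    zMat[i, ] <- pooled$z
    cMat[i, ] <- pooled$counts
  }
  new("DistanceCorrelation", z = zMat, counts = cMat, binUpperUm = edges,
    epochIndex = as.integer(epochs), epochS = grid@epochS,
    nSamples = grid@epochLength, band = band)
}

#' Analytic significance of a Fisher z value
#'
#' 95% confidence interval \code{z +/- 1.96 / sqrt(n - 3)} for a Fisher
#' z-transformed correlation estimated from \code{n} samples, and whether
#' the value is significantly greater than zero (lower bound above 0). The
#' nominal sample count ignores autocorrelation, so intervals are
#' anti-conservative for autocorrelated signals; see the package vignette.
#'
#' @param z Fisher z value(s).
#' @param nSamples number of samples behind the correlation (> 3).
#' @return data.frame with columns \code{z}, \code{lower}, \code{upper},
#'   \code{significant}.
#' @export
correlationSignificance <- function(z, nSamples) {
  if (any(nSamples <= 3)) stop("need more than 3 samples for the analytic CI")
  half <- 1.96 / sqrt(nSamples - 3)
  data.frame(z = z, lower = z - half, upper = z + half,
    significant = (z - half) > 0)
}

#' Narrowband correlation-by-distance functions
#'
#' Zero-phase band-pass filters the recording per band, then applies the
#' full distance-binning pipeline to each band-limited signal. Default
#' bands: delta 1-4, beta 16-24, low gamma 25-55, high gamma 65-140 Hz.
#'
#' @inheritParams distanceCorrelations
#' @param bands named list of band edges in Hz (all below Nyquist).
#' @return named list of [DistanceCorrelation-class] objects, one per band.
#' @export
narrowbandDistanceCorrelations <- function(rec, layout, grid,
    bands = list(delta = c(1, 4), beta = c(16, 24), lowgamma = c(25, 55),
      highgamma = c(65, 140)),
    binWidthUm = 600) {
  nyq <- samplingRate(rec) / 2
  for (b in names(bands)) {
    e <- bands[[b]]
    if (length(e) != 2L || e[1] <= 0 || e[2] <= e[1] || e[2] >= nyq)
      stop("invalid band edges for ", b)
  }
  out <- list()
  for (b in names(bands)) {
    nb <- initialize(rec,
      signal = bandLimit(rec@signal, samplingRate(rec), bands[[b]]))
    out[[b]] <- distanceCorrelations(nb, layout, grid, binWidthUm, band = b)
  }
  out
}
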