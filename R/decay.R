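#' @include AllClasses.R AllGenerics.R correlation.R
NULL

# Cap for the spatial decay constant: encodes "flat profile" without
# infinities.
.LAMBDA_CAP_UM <- 1e6

.dropNonPositive <- function(d, z, w) {
  bad <- !is.finite(z) | z <= 0
  if (any(bad & is.finite(z)))
    warning(sum(bad & is.finite(z)),
      " bin(s) with non-positive mean z dropped before log-domain fit")
  list(d = d[!bad], z = z[!bad], w = w[!bad])
}

.failedFit <- function(model) {
  data.frame(model = model, A = NA_real_, lambda_um = NA_real_,
    b = NA_real_, sigma_um = NA_real_, offset = NA_real_,
    slope = NA_real_, intercept = NA_real_, mse = NA_real_,
    nBins = 0L, flat = FALSE, converged = FALSE, ok = FALSE)
}

#' Fit an exponential spatial decay model
#'
#' Fits \eqn{f(d) = A e^{-d/\lambda}} to a Fisher z correlation-by-distance
#' profile by count-weighted linear regression in the log domain
#' (\code{ln z} on \code{d}): \eqn{A} is the initial value (Fisher z units
#' at zero distance) and \eqn{\lambda} the spatial decay constant (um).
#' A non-negative slope marks a flat profile: \eqn{\lambda} is capped at
#' 1e6 um and the \code{flat} flag set. Bins with non-positive mean z are
#' dropped with a warning; fewer than 2 usable bins is a recorded fit
#' failure (\code{ok = FALSE}), not an error. The reported \code{mse} is
#' the mean squared error on the z scale (not the log scale), so fits are
#' comparable across model families.
#'
#' @param d bin nominal distances (um).
#' @param z mean Fisher z per bin.
#' @param weights fit weights, proportional to per-bin observation counts
#'   (default equal weights).
#' @return one-row data.frame with the fitted parameters, \code{mse} and
#'   flags.
#' @examples
#' d <- seq(600, 4200, by = 600)
#' fitExponential(d, 1.2 * exp(-d / 4000))
#' @export
fitExponential <- function(d, z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  keep <- .dropNonPositive(d, z, weights)
  if (length(keep$z) < 2L) return(.failedFit("exponential"))
  fit <- stats::lm(log(keep$z) ~ keep$d, weights = keep$w)
  co <- stats::coef(fit)
  A <- exp(co[[1L]])
  slope <- co[[2L]]
  flat <- slope >= -1e-9
  lambda <- if (flat) .LAMBDA_CAP_UM else -1 / slope
  pred <- A * exp(-keep$d / lambda)
  out <- .failedFit("exponential")
  out$A <- A; out$lambda_um <- lambda; out$flat <- flat
  out$mse <- mean((keep$z - pred)^2)
  out$nBins <- length(keep$z); out$converged <- TRUE; out$ok <- TRUE
  out
}

#' Fit a power-law spatial decay model
#'
#' Fits \eqn{f(d) = A d^{-b}} by count-weighted linear regression of
#' \code{ln z} on \code{ln d}; \eqn{A} is the value at d = 1 um and
#' \eqn{b} the decay exponent. Same bin handling and z-scale MSE as
#' [fitExponential()].
#'
#' @inheritParams fitExponential
#' @return one-row data.frame.
#' @export
fitPowerLaw <- function(d, z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  if (any(d <= 0)) stop("power-law fit requires positive distances")
  keep <- .dropNonPositive(d, z, weights)
  if (length(keep$z) < 2L) return(.failedFit("powerlaw"))
  fit <- stats::lm(log(keep$z) ~ log(keep$d), weights = keep$w)
  co <- stats::coef(fit)
  A <- exp(co[[1L]])
  b <- -co[[2L]]
  pred <- A * keep$d^(-b)
  out <- .failedFit("powerlaw")
  out$A <- A; out$b <- b; out$flat <- b <= 1e-9
  out$mse <- mean((keep$z - pred)^2)
  out$nBins <- length(keep$z); out$converged <- TRUE; out$ok <- TRUE
  out
}

#' Fit a Gaussian spatial decay model
#'
#' Fits \eqn{f(d) = A e^{-d^2/(2\sigma^2)} + c} by count-weighted nonlinear
#' least squares (Levenberg-Marquardt), multi-started over
#' \eqn{\sigma \in \{1000, 2000, 4000\}} um with \code{A = max z - min z}
#' and \code{c = min z}; the best candidate is kept even when the optimizer
#' does not report convergence (flagged via \code{converged}).
#'
#' @inheritParams fitExponential
#' @return one-row data.frame (parameters in \code{A}, \code{sigma_um},
#'   \code{offset}).
#' @export
fitGaussian <- function(d, z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  keep <- !is.na(z)
  d <- d[keep]; z <- z[keep]; weights <- weights[keep]
  if (length(z) < 3L) return(.failedFit("gaussian"))
  best <- NULL
  for (s0 in c(1000, 2000, 4000)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ A * exp(-d^2 / (2 * sg^2)) + c0,
        start = list(A = max(z) - min(z), sg = s0, c0 = min(z)),
        weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(weights * stats::residuals(fit)^2)
    conv <- fit$convInfo$isConv
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse, conv = isTRUE(conv))
  }
  if (is.null(best)) return(.failedFit("gaussian"))
  co <- stats::coef(best$fit)
  pred <- co[["A"]] * exp(-d^2 / (2 * co[["sg"]]^2)) + co[["c0"]]
  out <- .failedFit("gaussian")
  out$A <- co[["A"]]; out$sigma_um <- abs(co[["sg"]]); out$offset <- co[["c0"]]
  out$mse <- mean((z - pred)^2)
  out$nBins <- length(z); out$converged <- best$conv; out$ok <- TRUE
  out
}

#' Fit a linear spatial decay model
#'
#' Count-weighted least squares of z on distance.
#'
#' @inheritParams fitExponential
#' @return one-row data.frame (parameters in \code{slope},
#'   \code{intercept}).
#' @export
fitLinear <- function(d, z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  keep <- !is.na(z)
  d <- d[keep]; z <- z[keep]; weights <- weights[keep]
  if (length(z) < 2L) return(.failedFit("linear"))
  fit <- stats::lm(z ~ d, weights = weights)
  co <- stats::coef(fit)
  pred <- co[[1L]] + co[[2L]] * d
  out <- .failedFit("linear")
  out$slope <- co[[2L]]; out$intercept <- co[[1L]]
  out$mse <- mean((z - pred)^2)
  out$nBins <- length(z); out$converged <- TRUE; out$ok <- TRUE
  out
}

#' Low-count bin exclusion rule
#'
#' Which bins survive the low-observation exclusion rule: a bin is dropped
#' when its count is below \code{thresholdFrac} times the mean count of the
#' other bins.
#'
#' @param counts per-bin observation counts.
#' @param thresholdFrac fraction in (0, 1), default 0.2.
#' @return logical vector, TRUE for retained bins.
#' @examples
#' lowCountKeep(c(100, 100, 100, 100, 5))  # last bin dropped
#' @export
lowCountKeep <- function(counts, thresholdFrac = 0.2) {
  stopifnot(thresholdFrac > 0, thresholdFrac < 1)
  n <- length(counts)
  if (n < 2L) return(rep(TRUE, n))
  othersMean <- (sum(counts) - counts) / (n - 1)
  keep <- counts >= thresholdFrac * othersMean
  if (!any(keep)) stop("low-count rule dropped every bin")
  keep
}

#' @describeIn lowCountKeep apply the rule to a whole
#'   [DistanceCorrelation-class]: dropped bins get count 0 and NA mean,
#'   per epoch.
#' @param fn a [DistanceCorrelation-class].
#' @export
excludeLowCountBins <- function(fn, thresholdFrac = 0.2) {
  stopifnot(is(fn, "DistanceCorrelation"))
  z <- fn@z
  counts <- fn@counts
  for (i in seq_len(nrow(z))) {
    keep <- lowCountKeep(counts[i, ], thresholdFrac)
    z[i, !keep] <- NA_real_
    counts[i, !keep] <- 0L
  }
  initialize(fn, z = z, counts = counts)
}

#' Fit decay models to every epoch of a DistanceCorrelation
#'
#' Applies the selected model fits to each epoch's correlation-by-distance
#' function, with weights proportional to per-bin observation counts and an
#' optional low-count exclusion rule applied first.
#'
#' @param fn a [DistanceCorrelation-class].
#' @param models subset of \code{c("exponential", "powerlaw", "gaussian",
#'   "linear")}.
#' @param excludeLowCountFrac optional fraction for [excludeLowCountBins()]
#'   (NULL, the default, applies no exclusion: the weighting already
#'   downweights sparse bins).
#' @return data.frame with one row per epoch per model (columns
#'   \code{epoch}, \code{model}, parameters, \code{mse}, flags).
#' @export
fitDecayModels <- function(fn, models = "exponential",
                           excludeLowCountFrac = NULL) {
  stopifnot(is(fn, "DistanceCorrelation"))
  models <- match.arg(models,
    c("exponential", "powerlaw", "gaussian", "linear"), several.ok = TRUE)
  if (!is.null(excludeLowCountFrac))
    fn <- excludeLowCountBins(fn, excludeLowCountFrac)
  fitters <- list(exponential = fitExponential, powerlaw = fitPowerLaw,
    gaussian = fitGaussian, linear = fitLinear)
  d <- binDistances(fn)
  rows <- vector("list", nrow(fn@z) * length(models))
  k <- 0L
  for (i in seq_len(nrow(fn@z))) {
    use <- fn@counts[i, ] > 0L & is.finite(fn@z[i, ])
    for (m in models) {
      k <- k + 1L
      row <- if (sum(use) >= 2L)
        fitters[[m]](d[use], fn@z[i, use], weights = fn@counts[i, use])
      else .failedFit(m)
      row$epoch <- epochIndices(fn)[i]
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("epoch", setdiff(names(out), "epoch"))]
}

#' Compare model families by mean squared error
#'
#' Summarizes per-epoch z-scale MSE distributions per model: mean MSE,
#' Gaussian-kernel density estimates (Silverman's bandwidth), and a paired
#' table of mean MSE differences.
#'
#' @param fits data.frame from [fitDecayModels()] with >= 2 epochs.
#' @return list with \code{mse} (named list of per-epoch MSE vectors),
#'   \code{meanMse} (named vector), \code{density} (named list of
#'   [stats::density] objects, NULL for degenerate distributions), and
#'   \code{pairwise} (data.frame of mean MSE differences).
#' @export
compareModels <- function(fits) {
  fits <- fits[fits$ok & is.finite(fits$mse), , drop = FALSE]
  models <- unique(fits$model)
  mse <- lapply(models, function(m) fits$mse[fits$model == m])
  names(mse) <- models
  if (any(vapply(mse, length, 1L) < 2L))
    stop("need at least 2 epochs per model")
  meanMse <- vapply(mse, mean, numeric(1))
  dens <- lapply(mse, function(v) {
    if (stats::sd(v) == 0) NULL else stats::density(v, bw = "nrd0")
  })
  pairs <- expand.grid(a = models, b = models, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
  pairs$meanDiff <- meanMse[pairs$a] - meanMse[pairs$b]
  list(mse = mse, meanMse = meanMse, density = dens,
    pairwise = pairs[, c("a", "b", "meanDiff")])
}

#' Type-2 (standardized major axis) regression
#'
#' Line fit acknowledging variance in both variables: the standardized
#' major axis estimate \code{slope = sign(r) * sd(y)/sd(x)},
#' \code{intercept = mean(y) - slope * mean(x)}, with a percentile
#' bootstrap 95% confidence interval on the slope from case resampling.
#'
#' @param x,y numeric series (>= 3 points, nonzero variance).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @return list with \code{slope}, \code{intercept}, \code{r},
#'   \code{slopeCI} (percentile 95%), \code{flagged} (TRUE when r = 0 and
#'   the slope sign is undefined).
#' @examples
#' type2Regression(1:10, 2 * (1:10) + 1, nBoot = 100, seed = 1)$slope
#' @export
type2Regression <- function(x, y, nBoot = 1000, seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  sma <- function(x, y) {
    r <- stats::cor(x, y)
    s <- sign(r)
    if (s == 0) s <- 1
    slope <- s * stats::sd(y) / stats::sd(x)
    c(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
  }
  est <- sma(x, y)
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(nBoot, {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
    else sma(x[i], y[i])[["slope"]]
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(slope = est[["slope"]], intercept = est[["intercept"]],
    r = est[["r"]], slopeCI = ci, flagged = est[["r"]] == 0)
}
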