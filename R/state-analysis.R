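#' @include AllClasses.R decay.R staging.R
NULL

#' Join fits, states and band powers on the epoch index
#'
#' Inner join of the per-epoch decay fits and the per-epoch state table.
#' Epochs present in only one input (failed fits, invalid epochs) are
#' excluded; the number excluded is attached as attribute
#' \code{"excluded"}. The merged table carries the parameter ratio
#' \code{param_ratio = lambda_um / A} (or \code{b / A} for power-law fits)
#' and the band-power ratio \code{power_ratio = gamma / delta}, oriented so
#' both ratios are low in SWS and high in REM/awake.
#'
#' @param fits data.frame from [fitDecayModels()] (one model).
#' @param states data.frame from [stageSleep()].
#' @param ratioOrientation \code{"gamma/delta"} (default) or
#'   \code{"delta/gamma"} for the band-power ratio.
#' @return merged data.frame, one row per epoch present in both inputs.
#' @export
joinEpochs <- function(fits, states, ratioOrientation = c("gamma/delta",
    "delta/gamma")) {
  ratioOrientation <- match.arg(ratioOrientation)
  if (length(unique(fits$model)) != 1L)
    stop("joinEpochs expects fits from a single model")
  ok <- fits[fits$ok, , drop = FALSE]
  merged <- merge(ok, states, by = "epoch")
  if (!nrow(merged)) stop("no epochs present in both fits and states")
  nExcluded <- (nrow(fits) - nrow(merged)) + (nrow(states) - nrow(merged))
  merged <- merged[order(merged$epoch), , drop = FALSE]
  merged$param_ratio <- if (merged$model[1L] == "powerlaw")
    merged$b / merged$A else merged$lambda_um / merged$A
  merged$power_ratio <- if (ratioOrientation == "gamma/delta")
    merged$gamma_power / merged$delta_power
  else merged$delta_power / merged$gamma_power
  attr(merged, "excluded") <- nExcluded
  rownames(merged) <- NULL
  merged
}

#' Correlation between parameter and band-power ratios
#'
#' Pearson correlation between the per-epoch fit-parameter ratio and band
#' power ratio, with the analytic Fisher 95% confidence interval
#' (\code{atanh(r) +/- 1.96/sqrt(n-3)}, back-transformed) and the Type-2
#' (standardized major axis) regression slope with its bootstrap CI.
#'
#' @param paramRatio,powerRatio per-epoch ratio series (>= 4 epochs).
#' @param nBoot bootstrap resamples for the slope CI.
#' @param seed optional integer seed.
#' @return list with \code{r}, \code{rCI}, \code{n}, and \code{type2}
#'   (see [type2Regression()]).
#' @export
correlateRatios <- function(paramRatio, powerRatio, nBoot = 1000,
                            seed = NULL) {
  keep <- is.finite(paramRatio) & is.finite(powerRatio)
  x <- paramRatio[keep]; y <- powerRatio[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 epochs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  zci <- atanh(r) + c(-1, 1) * 1.96 / sqrt(n - 3)
  list(r = r, rCI = tanh(zci), n = n,
    type2 = type2Regression(x, y, nBoot = nBoot, seed = seed))
}

#' d-prime separation between two groups
#'
#' \eqn{d' = |\bar a - \bar b| / \sqrt{(s_a^2 + s_b^2)/2}} with
#' sample variances (denominator n-1). Both groups zero-variance with
#' different means gives Inf (flagged by the caller's judgement); equal
#' means give 0.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return d-prime value.
#' @examples
#' dprime(rnorm(100), rnorm(100, 2))
#' @export
dprime <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
  dm <- abs(mean(a) - mean(b))
  if (pooled == 0) {
    if (dm == 0) return(0)
    warning("zero variance in both groups with different means; d' infinite")
    return(Inf)
  }
  dm / pooled
}

#' Coefficient of variation with bootstrap CI
#'
#' CV = SD/mean (positive mean required), with a percentile bootstrap 95%
#' confidence interval from iid case resampling.
#'
#' @param values numeric vector (>= 3 values, positive mean).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{cv}, \code{ci}, \code{n}.
#' @examples
#' coefficientOfVariation(c(1, 2, 3), nBoot = 200, seed = 1)$cv  # 0.5
#' @export
coefficientOfVariation <- function(values, nBoot = 1000, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (mean(values) <= 0) stop("CV requires a positive mean")
  cv <- stats::sd(values) / mean(values)
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(nBoot, {
    v <- values[sample.int(length(values), replace = TRUE)]
    if (mean(v) <= 0) NA_real_ else stats::sd(v) / mean(v)
  })
  list(cv = cv,
    ci = stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    n = length(values))
}

#' Per-state kernel density estimates on a shared grid
#'
#' Gaussian kernel, Silverman's bandwidth, evaluated on one grid spanning
#' all states so densities are directly comparable; each density
#' integrates to 1 (trapezoid rule) within numerical tolerance.
#' Single-point states are returned flagged with a NULL density.
#'
#' @param values numeric vector of per-epoch values.
#' @param states character vector of state labels, same length.
#' @param gridN number of evaluation points (default 512).
#' @return named list per state: list with \code{x}, \code{y}, \code{n},
#'   \code{flagged}.
#' @export
stateDensities <- function(values, states, gridN = 512L) {
  keep <- is.finite(values)
  values <- values[keep]; states <- states[keep]
  rng <- range(values)
  pad <- diff(rng) * 0.15 + 1e-12
  lo <- rng[1] - pad; hi <- rng[2] + pad
  out <- list()
  for (s in unique(states)) {
    v <- values[states == s]
    if (length(v) < 2L) {
      out[[s]] <- list(x = NULL, y = NULL, n = length(v), flagged = TRUE)
      next
    }
    d <- stats::density(v, bw = "nrd0", from = lo, to = hi, n = gridN)
    out[[s]] <- list(x = d$x, y = d$y, n = length(v), flagged = FALSE)
  }
  out
}

#' Per-state parameter summaries
#'
#' Mean and SD of the spatial decay constant and of the parameter ratio per
#' state, with sample sizes and the ratio's CV with bootstrap CI. States
#' absent from the table are omitted with a note attribute.
#'
#' @param merged data.frame from [joinEpochs()].
#' @param nBoot bootstrap resamples for the CV intervals.
#' @param seed optional integer seed.
#' @return data.frame with one row per observed state.
#' @export
stateParameterSummary <- function(merged, nBoot = 1000, seed = NULL) {
  rows <- list()
  for (s in SLEEP_STATES) {
    v <- merged[merged$state == s, , drop = FALSE]
    if (!nrow(v)) next
    cv <- if (nrow(v) >= 3L && mean(v$param_ratio) > 0)
      coefficientOfVariation(v$param_ratio, nBoot = nBoot, seed = seed)
    else list(cv = NA_real_, ci = c(NA_real_, NA_real_))
    rows[[s]] <- data.frame(state = s, n = nrow(v),
      lambda_mean = mean(v$lambda_um), lambda_sd = stats::sd(v$lambda_um),
      ratio_mean = mean(v$param_ratio), ratio_sd = stats::sd(v$param_ratio),
      ratio_cv = cv$cv, ratio_cv_lo = cv$ci[1], ratio_cv_hi = cv$ci[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  missing <- setdiff(SLEEP_STATES, out$state)
  if (length(missing)) attr(out, "note") <-
    paste("states not observed:", paste(missing, collapse = ", "))
  out
}
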