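#' @include AllClasses.R
NULL

# Moving average with shrinking windows at the edges.
.movingAverage <- function(x, width) {
  if (width == 1L) return(x)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Predict SWS epochs with a threshold model
#'
#' Smooths the parameter series with a centered moving average (shrinking
#' windows at the edges), then thresholds it in the model's direction
#' (\code{"below"}: values at or below the threshold are called SWS).
#'
#' @param values per-epoch parameter series.
#' @param model list with \code{threshold}, \code{width} (odd positive
#'   integer) and \code{direction} (\code{"below"} or \code{"above"}).
#' @return logical vector: TRUE where SWS is predicted.
#' @export
predictThreshold <- function(values, model) {
  stopifnot(is.list(model), model$width >= 1L, model$width %% 2L == 1L)
  s <- .movingAverage(values, as.integer(model$width))
  if (model$direction == "below") s <= model$threshold
  else s >= model$threshold
}

.gridError <- function(sessions, model) {
  errs <- vapply(sessions, function(ss) {
    mean(predictThreshold(ss$values, model) != ss$sws)
  }, numeric(1))
  mean(errs)
}

#' Leave-one-session-out training of the SWS threshold model
#'
#' For each held-out session, selects the (threshold, smoothing,
#' direction) triple minimizing the mean per-session misclassification
#' error over the remaining sessions, searching a grid of pooled-parameter
#' quantile thresholds and odd smoothing widths. Ties are broken by
#' smaller smoothing width, then smaller threshold, then direction
#' (\code{"below"} first: the SWS-typical direction for ratio parameters).
#'
#' @param sessions list of sessions, each a list with \code{values}
#'   (numeric per-epoch parameter series) and \code{sws} (logical SWS
#'   labels). At least 2 sessions required.
#' @param nThresholds number of pooled-quantile threshold candidates
#'   (default 50); midpoints of adjacent quantiles are added so a wide
#'   separating gap between classes is never skipped.
#' @param smoothGrid odd moving-average widths to search (default
#'   1, 3, 5, 7, 9 epochs).
#' @param thresholds optional explicit threshold candidates, overriding
#'   the quantile grid.
#' @return list with one element per held-out session: \code{model}
#'   (threshold, width, direction), \code{trainError}, \code{testError},
#'   \code{predictions} on the held-out session.
#' @export
trainThresholdLOO <- function(sessions, nThresholds = 50L,
                              smoothGrid = c(1L, 3L, 5L, 7L, 9L),
                              thresholds = NULL) {
  if (length(sessions) < 2L) stop("leave-one-out needs at least 2 sessions")
  if (any(smoothGrid %% 2L != 1L)) stop("smoothing widths must be odd")
  fixedThresholds <- thresholds
  lapply(seq_along(sessions), function(hold) {
    train <- sessions[-hold]
    pooled <- unlist(lapply(train, `[[`, "values"))
    thresholds <- if (is.null(fixedThresholds)) {
      q <- unique(stats::quantile(pooled,
        probs = seq(0, 1, length.out = nThresholds), names = FALSE))
      unique(sort(c(q, (q[-1L] + q[-length(q)]) / 2)))
    } else fixedThresholds
    best <- NULL
    for (w in sort(smoothGrid)) for (thr in sort(thresholds))
      for (dir in c("below", "above")) {
        model <- list(threshold = thr, width = as.integer(w),
          direction = dir)
        err <- .gridError(train, model)
        if (is.null(best) || err < best$trainError - 1e-12) {
          best <- list(model = model, trainError = err)
        }
      }
    pred <- predictThreshold(sessions[[hold]]$values, best$model)
    list(model = best$model, trainError = best$trainError,
      testError = mean(pred != sessions[[hold]]$sws), predictions = pred)
  })
}

#' Label-shuffle null distribution for the threshold model
#'
#' Permutes the SWS labels uniformly per shuffle and recomputes the
#' model's misclassification error against the shuffled labels, giving the
#' null error distribution under label exchangeability.
#'
#' @param values per-epoch parameter series.
#' @param labels logical SWS labels.
#' @param model threshold model (see [predictThreshold()]).
#' @param nShuffles number of shuffles (>= 100).
#' @param seed optional integer seed.
#' @return list with \code{observed} error, \code{nullErrors},
#'   \code{nullMean}, \code{interval} (central 95%), \code{rank} of the
#'   observed error among the null draws, and the empirical
#'   \code{pValue} = P(null <= observed).
#' @export
shuffleNull <- function(values, labels, model, nShuffles = 1000L,
                        seed = NULL) {
  if (nShuffles < 100L) stop("need at least 100 shuffles")
  if (length(values) != length(labels)) stop("length mismatch")
  pred <- predictThreshold(values, model)
  observed <- mean(pred != labels)
  if (!is.null(seed)) set.seed(seed)
  nullErrors <- replicate(nShuffles, mean(pred != sample(labels)))
  list(observed = observed, nullErrors = nullErrors,
    nullMean = mean(nullErrors),
    interval = stats::quantile(nullErrors, c(0.025, 0.975), names = FALSE),
    rank = sum(nullErrors < observed) + 1L,
    pValue = (sum(nullErrors <= observed) + 1L) / (nShuffles + 1L))
}

#' Accuracy, precision and confusion counts
#'
#' Accuracy is the proportion of hits and correct rejections; precision
#' the proportion of hits among all positive predictions (NA when there
#' are no positive predictions).
#'
#' @param pred,truth logical vectors of equal length (TRUE = SWS).
#' @return list with \code{accuracy}, \code{precision}, and confusion
#'   counts \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @examples
#' accuracyPrecision(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
accuracyPrecision <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  list(accuracy = (tp + tn) / length(pred),
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    tp = tp, tn = tn, fp = fp, fn = fn)
}
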