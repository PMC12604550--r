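test_that("prediction smooths then thresholds", {
  model <- list(threshold = 0.5, width = 1L, direction = "above")
  expect_equal(predictThreshold(c(0, 1, 0.4, 0.6), model),
    c(FALSE, TRUE, FALSE, TRUE))

  # constant series above threshold: all SWS
  expect_true(all(predictThreshold(rep(2, 5), model)))

  # step series, width 3: transition epochs follow the window majority;
  # hand-computed smoothed values (0, 0, 1/3, 2/3, 1, 1)
  m3 <- list(threshold = 0.5, width = 3L, direction = "above")
  expect_equal(predictThreshold(c(0, 0, 0, 1, 1, 1), m3),
    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(slowwave:::.movingAverage(c(0, 0, 0, 1, 1, 1), 3L),
    c(0, 0, 1 / 3, 2 / 3, 1, 1))

  expect_error(predictThreshold(1:5, list(threshold = 0, width = 2L,
    direction = "above")))
})

test_that("leave-one-out training finds separating thresholds", {
  # perfectly separable parameter: zero train and test error
  set.seed(24)
  mk <- function() {
    sws <- rep(c(TRUE, FALSE), each = 30)
    list(values = ifelse(sws, rnorm(60, 0, 0.1), rnorm(60, 5, 0.1)),
      sws = sws)
  }
  sessions <- list(mk(), mk(), mk())
  folds <- trainThresholdLOO(sessions)
  expect_true(all(vapply(folds, `[[`, 1, "trainError") == 0))
  expect_true(all(vapply(folds, `[[`, 1, "testError") == 0))
  expect_true(all(vapply(folds, function(f) f$model$direction, "") ==
    "below"))

  # duplicated sessions: identical model per fold
  dup <- list(sessions[[1]], sessions[[1]], sessions[[1]])
  fd <- trainThresholdLOO(dup)
  expect_equal(fd[[1]]$model, fd[[2]]$model)
  expect_equal(fd[[2]]$model, fd[[3]]$model)

  # labels independent of the parameter: test error near the
  # best-constant-classifier bound min(p, 1-p)
  set.seed(25)
  mkNull <- function() list(values = rnorm(400),
    sws = runif(400) < 0.3)
  nullSessions <- list(mkNull(), mkNull(), mkNull(), mkNull())
  nf <- trainThresholdLOO(nullSessions)
  testErr <- mean(vapply(nf, `[[`, 1, "testError"))
  expect_equal(testErr, 0.3, tolerance = 0.2)

  expect_error(trainThresholdLOO(sessions[1]), "2 sessions")
})

test_that("finer threshold grids never increase training error", {
  set.seed(26)
  sessions <- lapply(1:3, function(i) {
    sws <- runif(100) < 0.4
    list(values = rnorm(100) - sws * 1.2, sws = sws)
  })
  # explicitly nested candidate grids: refinement is a superset
  pooledAll <- unlist(lapply(sessions, `[[`, "values"))
  gridA <- quantile(pooledAll, seq(0, 1, length.out = 20), names = FALSE)
  gridB <- sort(c(gridA, quantile(pooledAll, seq(0.025, 0.975,
    length.out = 39), names = FALSE)))
  coarse <- trainThresholdLOO(sessions, thresholds = gridA)
  fine <- trainThresholdLOO(sessions, thresholds = gridB)
  for (i in seq_along(sessions)) {
    expect_lte(fine[[i]]$trainError, coarse[[i]]$trainError + 1e-12)
  }
})

test_that("shuffle null is centered and calibrated", {
  # perfect predictor at prevalence 0.5: observed 0, null near 0.5
  values <- rep(c(0, 1), 50)
  labels <- values == 0
  model <- list(threshold = 0.5, width = 1L, direction = "below")
  sn <- shuffleNull(values, labels, model, nShuffles = 500, seed = 1)
  expect_equal(sn$observed, 0)
  expect_equal(sn$nullMean, 0.5, tolerance = 0.05)
  expect_equal(sn$rank, 1L)

  expect_error(shuffleNull(values, labels, model, nShuffles = 0), "100")
  expect_error(shuffleNull(values, labels[-1], model), "mismatch")

  # calibration: for label-independent parameters the observed error
  # falls inside the null 95% interval in >= 90% of runs
  set.seed(27)
  inside <- replicate(40, {
    v <- rnorm(150)
    l <- runif(150) < 0.4
    m <- list(threshold = median(v), width = 1L, direction = "below")
    s <- shuffleNull(v, l, m, nShuffles = 200)
    s$observed >= s$interval[1] && s$observed <= s$interval[2]
  })
  expect_gte(mean(inside), 0.9)
})

test_that("accuracy and precision follow their definitions", {
  pred <- c(rep(TRUE, 10), rep(FALSE, 90))
  truth <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 10), rep(FALSE, 80))
  ap <- accuracyPrecision(pred, truth)
  expect_equal(ap$tp, 8); expect_equal(ap$fp, 2)
  expect_equal(ap$fn, 10); expect_equal(ap$tn, 80)
  expect_equal(ap$accuracy, 0.88)
  expect_equal(ap$precision, 0.8)

  perfect <- accuracyPrecision(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)

  none <- accuracyPrecision(rep(FALSE, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 0.75)
  expect_error(accuracyPrecision(pred, truth[-1]), "mismatch")
})
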