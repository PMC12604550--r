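test_that("exponential fits recover noiseless model data exactly", {
  d <- seq(600, 4200, by = 600)
  z <- 1.2 * exp(-d / 4000)
  fit <- fitExponential(d, z)
  expect_equal(fit$A, 1.2, tolerance = 1e-9)
  expect_equal(fit$lambda_um, 4000, tolerance = 1e-9)
  expect_equal(fit$mse, 0, tolerance = 1e-18)
  expect_false(fit$flat)

  # constant profile: flat flag, lambda capped, A recovered
  flat <- fitExponential(d, rep(0.8, length(d)))
  expect_true(flat$flat)
  expect_equal(flat$A, 0.8, tolerance = 1e-9)
  expect_equal(flat$lambda_um, 1e6)

  # non-positive bins dropped with warning; too few bins is a recorded
  # failure, not an error
  expect_warning(fit2 <- fitExponential(d, c(z[1:6], -0.1)), "dropped")
  expect_true(fit2$ok)
  expect_equal(fit2$nBins, 6L)
  expect_warning(bad <- fitExponential(d[1:2], c(0.5, -1)), "dropped")
  expect_false(bad$ok)
})

test_that("zero-weight bins are equivalent to omitted bins", {
  set.seed(12)
  d <- seq(600, 4200, by = 600)
  z <- 1.1 * exp(-d / 3500) * exp(rnorm(7, 0, 0.05))
  w <- c(10, 10, 10, 0, 10, 10, 10)
  a <- fitExponential(d, z, weights = w)
  b <- fitExponential(d[-4], z[-4], weights = w[-4])
  expect_equal(a$A, b$A, tolerance = 1e-12)
  expect_equal(a$lambda_um, b$lambda_um, tolerance = 1e-12)
})

test_that("weighted log-domain fits match a grid-search oracle", {
  # independent oracle: dense grid over (ln A, slope) minimizing the
  # weighted log-domain SSE
  gridSearch <- function(d, z, w, trans = identity) {
    x <- trans(d)
    lnz <- log(z)
    best <- c(Inf, NA, NA)
    for (lnA in seq(-1, 1, by = 0.002)) {
      # profile the slope on the grid too
      for (sl in seq(-8e-4, 0, by = 2e-6)) {
        sse <- sum(w * (lnz - (lnA + sl * x))^2)
        if (sse < best[1]) best <- c(sse, lnA, sl)
      }
    }
    best
  }
  set.seed(13)
  d <- seq(600, 4200, by = 600)
  z <- 1.3 * exp(-d / 4200) * exp(rnorm(7, 0, 0.08))
  w <- c(30, 40, 38, 35, 25, 12, 5)
  fit <- fitExponential(d, z, weights = w)
  oracle <- gridSearch(d, z, w)
  sse <- function(lnA, sl) sum(w * (log(z) - (lnA + sl * d))^2)
  # the analytic optimum is at least as good as the best grid point, and
  # the parameters agree within the (coupled) grid resolution
  expect_lte(sse(log(fit$A), -1 / fit$lambda_um), oracle[1] + 1e-12)
  expect_lt(abs(log(fit$A) - oracle[2]), 0.01)
  expect_lt(abs(-1 / fit$lambda_um - oracle[3]), 1e-5)

  # power law: same oracle on ln d (slope range rescaled)
  zp <- 40 * d^(-0.55) * exp(rnorm(7, 0, 0.08))
  fitP <- fitPowerLaw(d, zp, weights = w)
  lnd <- log(d)
  best <- c(Inf, NA, NA)
  for (lnA in seq(2, 6, by = 0.004)) for (sl in seq(-1.2, 0, by = 0.002)) {
    s <- sum(w * (log(zp) - (lnA + sl * lnd))^2)
    if (s < best[1]) best <- c(s, lnA, sl)
  }
  expect_lte(sum(w * (log(zp) - (log(fitP$A) - fitP$b * lnd))^2),
    best[1] + 1e-12)
  expect_lt(abs(log(fitP$A) - best[2]), 0.02)
  expect_lt(abs(-fitP$b - best[3]), 0.01)
})

test_that("power-law fits recover noiseless model data exactly", {
  d <- seq(600, 4200, by = 600)
  z <- 50 * d^(-0.6)
  fit <- fitPowerLaw(d, z)
  expect_equal(fit$A, 50, tolerance = 1e-9)
  expect_equal(fit$b, 0.6, tolerance = 1e-12)
  expect_equal(fitPowerLaw(d, rep(0.7, 7))$b, 0, tolerance = 1e-12)
})

test_that("gaussian and linear fits behave on model data", {
  d <- seq(600, 4200, by = 600)
  zl <- 1.5 - 2e-4 * d
  lin <- fitLinear(d, zl)
  expect_equal(lin$slope, -2e-4, tolerance = 1e-12)
  expect_equal(lin$intercept, 1.5, tolerance = 1e-12)
  expect_equal(lin$mse, 0, tolerance = 1e-20)

  zg <- 0.9 * exp(-d^2 / (2 * 2500^2)) + 0.3
  g <- fitGaussian(d, zg)
  expect_equal(g$A, 0.9, tolerance = 1e-6)
  expect_equal(g$sigma_um, 2500, tolerance = 1e-3)
  expect_equal(g$offset, 0.3, tolerance = 1e-6)
  expect_true(g$converged)

  # exponential-generated data: linear model must fit worse
  ze <- 1.2 * exp(-d / 3000)
  expect_gt(fitLinear(d, ze)$mse, fitExponential(d, ze)$mse)
})

test_that("model comparison aggregates MSE distributions", {
  ana <- cachedAnalysis(40, 101)
  cmp <- compareModels(ana$fits)
  expect_named(cmp$meanMse, c("exponential", "linear"), ignore.order = TRUE)
  # generator profiles are exponential-family: exponential beats linear
  expect_lte(cmp$meanMse[["exponential"]], cmp$meanMse[["linear"]])
  expect_s3_class(cmp$density$exponential, "density")

  # linearity of the mean
  f <- data.frame(model = rep(c("a", "b"), each = 5),
    mse = c(1:5 / 2, 1:5), ok = TRUE)
  cmp2 <- compareModels(f)
  expect_equal(cmp2$meanMse[["a"]], cmp2$meanMse[["b"]] / 2)

  # degenerate identical values: NULL density, mean preserved
  f3 <- data.frame(model = "a", mse = rep(0.25, 4), ok = TRUE)
  cmp3 <- compareModels(f3)
  expect_null(cmp3$density$a)
  expect_equal(cmp3$meanMse[["a"]], 0.25)
})

test_that("low-count exclusion drops only sparse bins", {
  expect_equal(lowCountKeep(c(100, 100, 100, 100, 5)),
    c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(lowCountKeep(rep(42, 9))))
  # the bin with the largest count always survives (frac < 1), so the rule
  # can never empty the profile on its own
  expect_true(any(lowCountKeep(c(1, 2, 500, 400))))

  # no-op on uniformly well-observed data: identical fits
  ana <- cachedAnalysis(40, 101)
  dense <- ana$fn
  keepBins <- which(colSums(binCounts(dense)) / nrow(zMatrix(dense)) > 200)
  dense@z <- dense@z[, keepBins, drop = FALSE]
  dense@counts <- dense@counts[, keepBins, drop = FALSE]
  dense@binUpperUm <- dense@binUpperUm[keepBins]
  a <- fitDecayModels(dense, models = "exponential")
  b <- fitDecayModels(dense, models = "exponential",
    excludeLowCountFrac = 0.2)
  expect_equal(a, b)
})

test_that("fits are scale-equivariant in distance", {
  set.seed(14)
  d <- seq(600, 4200, by = 600)
  z <- 1.2 * exp(-d / 4000) * exp(rnorm(7, 0, 0.03))
  w <- 7:1
  f1 <- fitExponential(d, z, w)
  f2 <- fitExponential(3 * d, z, w)
  expect_equal(f2$lambda_um, 3 * f1$lambda_um, tolerance = 1e-9)
  expect_equal(f2$A, f1$A, tolerance = 1e-9)
  p1 <- fitPowerLaw(d, z, w)
  p2 <- fitPowerLaw(3 * d, z, w)
  expect_equal(p2$b, p1$b, tolerance = 1e-9)
})

test_that("type-2 regression matches closed forms and excludes zero", {
  x <- 1:10
  t2 <- type2Regression(x, 2 * x + 1, nBoot = 100, seed = 1)
  expect_equal(t2$slope, 2, tolerance = 1e-12)
  expect_equal(t2$intercept, 1, tolerance = 1e-12)

  # slope = sign(r) * sd(y)/sd(x)
  set.seed(15)
  xs <- rnorm(200)
  ys <- -3 * xs + rnorm(200, 0, 0.5)
  t2b <- type2Regression(xs, ys, nBoot = 100, seed = 2)
  expect_equal(t2b$slope, -sd(ys) / sd(xs), tolerance = 1e-9)

  # anticorrelated (A, lambda) cloud: CI excludes 0 and holds the estimate
  set.seed(16)
  A <- runif(150, 0.8, 1.5)
  lam <- 9000 - 3500 * A + rnorm(150, 0, 300)
  t2c <- type2Regression(A, lam, nBoot = 500, seed = 3)
  expect_lt(t2c$slopeCI[2], 0)
  expect_true(t2c$slope >= t2c$slopeCI[1] && t2c$slope <= t2c$slopeCI[2])

  expect_error(type2Regression(rep(1, 5), 1:5), "variance")
  expect_error(type2Regression(1:2, 1:2), "3 points")
})
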