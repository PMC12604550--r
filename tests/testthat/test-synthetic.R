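test_that("state sequences follow the transition matrix", {
  # absorbing chain: identity transition keeps the initial state
  expect_equal(generateStateSequence(50, diag(3), seed = 1, init = "SWS"),
    rep("SWS", 50))

  # uniform transition: each state frequency within 1% of 1/3 at large n
  u <- matrix(1 / 3, 3, 3)
  s <- generateStateSequence(30000, u, seed = 2)
  freq <- table(factor(s, SLEEP_STATES)) / length(s)
  expect_true(all(abs(freq - 1 / 3) < 0.01))

  # geometric dwell: P(stay) = 0.9 gives mean SWS run length ~ 10
  P <- matrix(c(0.9, 0.0, 0.1,
                0.0, 0.5, 0.5,
                0.5, 0.25, 0.25), 3, 3, byrow = TRUE)
  s <- generateStateSequence(60000, P, seed = 3, init = "SWS")
  r <- rle(s)
  runs <- r$lengths[r$values == "SWS"]
  # drop the censored final run if it is SWS
  if (s[length(s)] == "SWS") runs <- runs[-length(runs)]
  expect_equal(mean(runs), 10, tolerance = 0.05)

  expect_error(generateStateSequence(10, matrix(1, 3, 3)), "stochastic")
  expect_error(generateStateSequence(10, diag(2)), "3 x 3")
})

test_that("generated epochs have the designed correlation structure", {
  lay <- toyLayout(5)
  p <- closedFormParams()

  # shared signal only: all pairwise correlations are 1
  p1 <- p
  p1$states$REM_AWAKE$amp <- list(
    delta = c(global = 0, spatial = 0, local = 0),
    gamma = c(global = 1, spatial = 0, local = 0))
  x <- generateEpoch(lay, "REM_AWAKE", p1, seed = 4)
  expect_equal(max(abs(cor(t(x)) - 1)), 0, tolerance = 1e-6)

  # independent noise only: sample correlations near 0
  p0 <- p
  p0$states$REM_AWAKE$amp <- list(
    delta = c(global = 0, spatial = 0, local = 0),
    gamma = c(global = 0, spatial = 0, local = 1))
  x <- generateEpoch(lay, "REM_AWAKE", p0, seed = 5)
  C <- cor(t(x))
  # band-limited noise has ~2*B*T effective dof, not n samples; bound the
  # max over 300 pairs at 5 null SDs
  expect_lt(max(abs(C[upper.tri(C)])), 5 / sqrt(2 * 30 * 10))
})

test_that("pairwise correlation matches the closed form rho*(d)", {
  # sigma_g = sigma_s = sigma_n, ell = 2000 um: rho*(d) = (1+e^{-d/ell})/3,
  # so rho*(2000) = (1+e^{-1})/3 ~ 0.456; Monte-Carlo over >= 100 epochs
  lay <- utahArrayLayout()
  p <- closedFormParams(ellUm = 2000)
  D <- electrodeDistances(lay)
  pairAt2000 <- which(abs(D - 2000) < 1e-6 & upper.tri(D), arr.ind = TRUE)
  expect_gt(nrow(pairAt2000), 0)
  set.seed(6)
  est <- replicate(100, {
    x <- generateEpoch(lay, "REM_AWAKE", p)
    C <- cor(t(x))
    mean(C[pairAt2000])
  })
  expect_equal(mean(est), (1 + exp(-1)) / 3, tolerance = 0.02 / 0.456)
})

test_that("sessions are deterministic, sized correctly, and empty-safe", {
  lay <- utahArrayLayout()
  p <- generatorParams(fs = 250, epochS = 10)

  s0 <- generateSession(lay, p, nEpochs = 0, seed = 1)
  expect_equal(nSamples(s0$recording), 0L)
  expect_length(stateLabels(s0$truth), 0)

  a <- generateSession(lay, p, nEpochs = 3, seed = 11)
  b <- generateSession(lay, p, nEpochs = 3, seed = 11)
  expect_identical(signalMatrix(a$recording), signalMatrix(b$recording))
  expect_identical(validMask(a$recording), validMask(b$recording))
  expect_identical(stateLabels(a$truth), stateLabels(b$truth))

  # n_epochs * epoch_s * fs samples exactly
  expect_equal(nSamples(a$recording), 3L * 10L * 250L)
  expect_equal(samplingRate(a$recording), 250)
})

test_that("dropout injection obeys rate, duration and mask contracts", {
  lay <- toyLayout(3)
  rec <- newRecording(matrix(rnorm(9 * 4000), 9), fs = 1000)

  # rate 0: no-op
  out <- injectDropouts(rec, rateHz = 0)
  expect_identical(out, rec)

  # one interval [2.0, 2.5) at 1 kHz: exactly 500 invalid samples
  out <- injectDropouts(rec,
    rateHz = 1, intervals = data.frame(start_s = 2, end_s = 2.5))
  expect_equal(sum(!validMask(out)), 500L)
  expect_true(all(signalMatrix(out)[, 2001:2500] == 0))
  iv <- maskIntervals(out)
  expect_equal(iv$start_s, 2)
  expect_equal(iv$end_s, 2.5)

  expect_error(injectDropouts(rec, rateHz = -1), "non-negative")

  # Poisson count: rate 0.02 Hz over 3600 s, count in the 95% band of
  # Poisson(72) (pure renewal process, burstiness 0)
  long <- newRecording(matrix(0, 1, 3600 * 100), fs = 100)
  counts <- vapply(1:8, function(s) {
    nrow(maskIntervals(injectDropouts(long, rateHz = 0.02,
      burstiness = 0, seed = s)))
  }, numeric(1))
  band <- qpois(c(0.025, 0.975), 72)
  expect_true(mean(counts >= band[1] & counts <= band[2]) >= 7 / 8)
})

test_that("generated states separate delta and gamma band power", {
  ana <- cachedAnalysis(40, 101)
  st <- ana$states
  truth <- ana$truthStates[match(st$epoch, epochIndices(ana$fn))]
  sws <- truth == "SWS"; rem <- truth == "REM_AWAKE"
  expect_gt(mean(st$delta_power[sws] > st$gamma_power[sws]), 0.95)
  expect_gt(mean(st$gamma_power[rem] > st$delta_power[rem]), 0.95)
})

test_that("ground truth profile is monotone, bounded, and serializes", {
  p <- generatorParams()
  d <- seq(0, 6000, by = 100)
  for (s in SLEEP_STATES) {
    rho <- expectedCorrelation(p, s, d)
    expect_true(all(diff(rho) <= 0))
    expect_true(all(rho >= 0 & rho <= 1))
  }
  st <- generatorParams()$states
  st$SWS$ellUm <- -1
  expect_error(generatorParams(states = st), "ellUm")
})
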