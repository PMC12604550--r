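test_that("electrode distances follow the grid geometry", {
  lay <- utahArrayLayout()
  D <- electrodeDistances(lay)
  expect_equal(nrow(D), 96L)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # orthogonal neighbors at the pitch, diagonal at pitch*sqrt(2): both bin 1
  expect_true(400 %in% round(D, 6))
  expect_equal(min(D[D > 0]), 400)
  expect_true(any(abs(D - 400 * sqrt(2)) < 1e-6))
  expect_lte(max(D), 400 * sqrt(81 + 81))

  dup <- utahArrayLayout(2, 2, pitchUm = 400, unwired = "none")
  dup@positions[2, ] <- dup@positions[1, ]
  expect_error(electrodeDistances(dup), "duplicate")
})

test_that("per-bin pair counts match exhaustive enumeration", {
  lay <- utahArrayLayout()
  D <- electrodeDistances(lay)
  edges <- distanceBinEdges(max(D))
  # brute force: loop over all 4560 unordered pairs
  n <- nChannels(lay)
  expect_equal(choose(n, 2), 4560)
  brute <- integer(length(edges))
  pos <- electrodePositions(lay)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    b <- ceiling(d / 600)   # half-open bins (lower, upper]
    brute[b] <- brute[b] + 1L
  }
  C <- diag(n) * 0 + 0.5 + diag(n) * 0.5
  binned <- binByDistance(C, D, edges)
  # each pair is seen once from each of its two source electrodes
  expect_equal(colSums(binned$counts), 2L * brute)
})

test_that("Fisher transform has the closed-form properties", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)))
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_equal(inverseFisherZ(fisherZ(r)), r, tolerance = 1e-12)
  expect_warning(z1 <- fisherZ(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("epoch correlation matrices behave at the extremes", {
  x <- rnorm(1000)
  rec <- newRecording(rbind(x, x, -x), fs = 100)
  grid <- buildEpochGrid(rec, 10)
  C <- epochCorrelationMatrix(rec, grid, 1)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(unname(diag(C)), rep(1, 3))

  set.seed(9)
  rec2 <- newRecording(matrix(rnorm(2 * 10000), 2), fs = 1000)
  C2 <- epochCorrelationMatrix(rec2, buildEpochGrid(rec2, 10), 1)
  expect_lt(abs(C2[1, 2]), 0.04)

  bad <- injectDropouts(rec, rateHz = 1,
    intervals = data.frame(start_s = 0.5, end_s = 0.6))
  expect_error(
    epochCorrelationMatrix(bad, buildEpochGrid(bad, 10), 1), "invalid")
})

test_that("binned weighted averages match a brute-force per-pair loop", {
  # toy 4x4 layout: independent per-pair loop reproduces the pipeline
  lay <- toyLayout(4)
  n <- nChannels(lay)
  set.seed(10)
  x <- matrix(rnorm(n * 500), n)
  C <- cor(t(x))
  D <- electrodeDistances(lay)
  edges <- distanceBinEdges(max(D))
  binned <- binByDistance(C, D, edges)
  pooled <- arrayAverage(binned)

  # brute force: for every source, every partner, accumulate z by bin
  sums <- matrix(0, n, length(edges))
  counts <- matrix(0L, n, length(edges))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    b <- ceiling(D[i, j] / 600)
    sums[i, b] <- sums[i, b] + atanh(C[i, j])
    counts[i, b] <- counts[i, b] + 1L
  }
  bruteMean <- sums / counts
  expect_equal(binned$counts, counts)
  expect_equal(binned$z[counts > 0], bruteMean[counts > 0],
    tolerance = 1e-12)
  bruteArray <- colSums(sums) / colSums(counts)
  expect_equal(pooled$z[pooled$counts > 0],
    bruteArray[colSums(counts) > 0], tolerance = 1e-12)

  # constant correlation field: every bin mean is atanh(r0)
  C0 <- matrix(0.4, n, n); diag(C0) <- 1
  b0 <- binByDistance(C0, D, edges)
  expect_true(all(abs(na.omit(as.vector(b0$z)) - atanh(0.4)) < 1e-12))

  # empty bins carry count 0 and NA mean (corner source, long distances)
  expect_true(any(b0$counts == 0L))
  expect_true(all(is.na(b0$z[b0$counts == 0L])))
})

test_that("count conservation holds on every epoch", {
  ana <- cachedAnalysis(40, 101)
  nPairs <- choose(96 - length(excludedChannels(ana$rec)), 2)
  expect_true(all(rowSums(binCounts(ana$fn)) == 2L * nPairs))
})

test_that("weighted averaging follows the arithmetic contract", {
  binned <- list(z = rbind(c(1, NA), c(2, NA)),
    counts = rbind(c(4L, 0L), c(1L, 0L)))
  pooled <- arrayAverage(binned)
  expect_equal(pooled$z[1], 1.2)           # (4*1 + 1*2) / 5
  expect_equal(pooled$counts, c(5L, 0L))
  expect_true(is.na(pooled$z[2]))          # all-empty bin marked missing

  # equal counts reduce to the unweighted mean
  binned2 <- list(z = rbind(c(1, 3), c(2, 5)),
    counts = rbind(c(2L, 2L), c(2L, 2L)))
  expect_equal(arrayAverage(binned2)$z, c(1.5, 4))
})

test_that("analytic confidence intervals flag significance correctly", {
  expect_false(correlationSignificance(0, 100)$significant)
  ci <- correlationSignificance(0.5, 10000)
  expect_equal(ci$upper - ci$z, 1.96 / sqrt(9997))
  expect_true(ci$significant)
  ci2 <- correlationSignificance(0.01, 100)
  expect_equal(ci2$z - ci2$lower, 1.96 / sqrt(97), tolerance = 1e-12)
  expect_false(ci2$significant)
  expect_error(correlationSignificance(0.5, 3), "samples")
})

test_that("pooled bin means are monotone non-increasing on generator output", {
  ana <- cachedAnalysis(40, 101)
  z <- zMatrix(ana$fn); cnt <- binCounts(ana$fn)
  pooled <- colSums(z * cnt) / colSums(cnt)
  # allow small sampling wiggle at the sparse far bins
  expect_true(all(diff(pooled) < 0.03))
  expect_gt(pooled[1], pooled[7])
})

test_that("narrowband functions isolate the band carrying the structure", {
  # structure (global+spatial) only in the delta component; gamma local-only
  lay <- utahArrayLayout()
  p <- generatorParams()
  p$states$SWS$amp <- list(
    delta = c(global = 0.5, spatial = 0.8, local = 0.15),
    gamma = c(global = 0, spatial = 0, local = 0.3))
  sess <- generateSession(lay, p, nEpochs = 6, seed = 21, init = "SWS",
    dropouts = FALSE)
  rec <- zscoreChannels(sess$recording)
  grid <- buildEpochGrid(rec, 10)
  nb <- narrowbandDistanceCorrelations(rec, lay, grid,
    bands = list(delta = c(1, 4), lowgamma = c(25, 55)))
  pool <- function(fn) {
    z <- zMatrix(fn); cnt <- binCounts(fn)
    inverseFisherZ(colSums(z * cnt) / colSums(cnt))
  }
  rhoDelta <- pool(nb$delta)
  rhoGamma <- pool(nb$lowgamma)
  expect_gt(rhoDelta[7], 0.4)        # delta band keeps the plateau
  expect_lt(abs(rhoGamma[7]), 0.15)  # gamma band decays toward zero
  expect_gt(rhoDelta[1], rhoGamma[1])

  expect_error(narrowbandDistanceCorrelations(rec, lay, grid,
    bands = list(bad = c(50, 200))), "band")
})

test_that("shorter epochs raise variance with only a modest mean drop", {
  sess <- cachedSession(40, 101)
  rec <- zscoreChannels(sess$recording)
  lay <- utahArrayLayout()
  stat <- function(epochS) {
    fn <- distanceCorrelations(rec, lay, buildEpochGrid(rec, epochS))
    z <- zMatrix(fn)
    c(var = mean(apply(z, 2, var)), mean = mean(z))
  }
  s1 <- stat(1)
  s6 <- stat(6)
  expect_gt(s1[["var"]], s6[["var"]])
  expect_lt(s6[["mean"]] - s1[["mean"]], 0.2 * s6[["mean"]])
  expect_gt(s1[["mean"]], 0)
})
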