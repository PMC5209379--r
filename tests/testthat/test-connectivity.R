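# Featurization chain: nuisance regression, band-pass filtering, Pearson
# correlation, Fisher z, canonical pair vectorization.

test_that("nuisance regression produces exact OLS residuals", {
  withr::local_seed(11)
  ts <- roiTimeSeries(matrix(rnorm(100 * 4), 100, 4), tr = 2)

  # intercept-only: plain demeaning
  out <- nuisanceRegress(ts)
  expect_equal(out@values, scale(ts@values, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)

  # a column identical to a regressor is annihilated
  reg <- matrix(rnorm(100 * 2), 100, 2)
  ts2 <- roiTimeSeries(cbind(reg[, 1], ts@values[, -1]), tr = 2)
  out2 <- nuisanceRegress(ts2, reg)
  expect_lt(max(abs(out2@values[, 1])), 1e-10)

  # residuals match the explicit normal-equations solution
  reg5 <- matrix(rnorm(100 * 5), 100, 5)
  Z <- cbind(1, reg5)
  oracle <- ts@values - Z %*% solve(crossprod(Z), crossprod(Z, ts@values))
  out3 <- nuisanceRegress(ts, reg5)
  expect_equal(out3@values, oracle, ignore_attr = TRUE, tolerance = 1e-10)

  # residual columns are orthogonal to every regressor
  ip <- crossprod(reg5, out3@values)
  norms <- outer(sqrt(colSums(reg5^2)), sqrt(colSums(out3@values^2)))
  expect_lt(max(abs(ip) / norms), 1e-8)

  # rank-deficient regressors: dependent columns dropped with a warning
  regDup <- cbind(reg5, reg5[, 1])
  expect_warning(out4 <- nuisanceRegress(ts, regDup), "rank-deficient")
  expect_equal(out4@values, oracle, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("band-pass filter passes, stops and conserves energy exactly", {
  n <- 200; tr <- 2
  t <- seq_len(n) - (n + 1) / 2          # centered time axis

  inBand <- cos(2 * pi * 0.05 * tr * t)  # 0.05 Hz, exact bin, even phase
  tsIn <- roiTimeSeries(cbind(inBand, rnorm(n)), tr = tr)
  keepRatio <- sd(bandpassFilter(tsIn)@values[, 1]) / sd(inBand)
  expect_gte(keepRatio, 0.99)

  outBand <- cos(2 * pi * 0.2 * tr * t)  # 0.2 Hz: outside 0.01-0.1
  tsOut <- roiTimeSeries(cbind(outBand, rnorm(n)), tr = tr)
  stopRatio <- sd(bandpassFilter(tsOut)@values[, 1]) / sd(outBand)
  expect_lte(stopRatio, 0.01)

  # Parseval: output energy equals the sum of retained periodogram
  # ordinates of the input
  withr::local_seed(4)
  x <- rnorm(n)
  filt <- bandpassFilter(roiTimeSeries(cbind(x, rnorm(n)), tr = tr))@values[, 1]
  freq <- (seq_len(n) - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)
  keep <- freq >= 0.01 & freq <= 0.1
  periodogram <- Mod(fft(x))^2 / n
  expect_equal(sum(filt^2), sum(periodogram[keep]), tolerance = 1e-8)

  # frequencies at or above Nyquist are rejected
  expect_error(bandpassFilter(tsIn, 0.01, 0.25), "Nyquist")
  expect_error(bandpassFilter(tsIn, 0.2, 0.1), "lowHz")
})

test_that("band-pass filter is idempotent", {
  withr::local_seed(5)
  ts <- roiTimeSeries(matrix(rnorm(150 * 3), 150, 3), tr = 2.5)
  once <- bandpassFilter(ts)
  twice <- bandpassFilter(once)
  expect_lt(max(abs(twice@values - once@values)), 1e-8)
})

test_that("correlation matrix matches the textbook formula", {
  withr::local_seed(6)
  v <- matrix(rnorm(50 * 4), 50, 4)
  ts <- roiTimeSeries(v, tr = 2)
  cm <- correlationMatrix(ts)
  oracle <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    x <- v[, i] - mean(v[, i]); y <- v[, j] - mean(v[, j])
    oracle[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  expect_equal(unname(cm), oracle, tolerance = 1e-12)

  dup <- roiTimeSeries(cbind(v[, 1], v[, 1], v[, 2]), tr = 2)
  expect_equal(correlationMatrix(dup)[1, 2], 1.0)
  neg <- roiTimeSeries(cbind(v[, 1], -v[, 1]), tr = 2)
  expect_equal(correlationMatrix(neg)[1, 2], -1.0)

  const <- roiTimeSeries(cbind(v[, 1], rep(1, 50)), tr = 2,
                         roiLabels = c("A", "FLAT"))
  expect_error(correlationMatrix(const), "FLAT")
})

test_that("Fisher z is the closed-form variance-stabilizing transform", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(-r), -fisherZ(r), tolerance = 1e-12)
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_true(all(is.finite(fisherZ(c(-1, 1)))))
  expect_error(fisherZ(1.5), "<= 1")
})

test_that("pair vectorization follows the canonical row-major order", {
  m84 <- diag(84)
  expect_length(vectorizePairs(m84), 3486)

  m3 <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  v3 <- vectorizePairs(m3)
  expect_equal(names(v3), c("a__b", "a__c", "b__c"))
  expect_equal(unname(v3), fisherZ(c(.1, .2, .3)), tolerance = 1e-12)

  # exhaustive index-pair round trip on a random symmetric matrix
  withr::local_seed(8)
  s <- cor(matrix(rnorm(40 * 10), 40, 10))
  v <- vectorizePairs(s)
  pt <- pairIndexTable(10)
  for (k in seq_len(nrow(pt)))
    expect_equal(unname(v[k]), fisherZ(s[pt$roi1[k], pt$roi2[k]]),
                 tolerance = 1e-12)

  asym <- s; asym[1, 2] <- asym[1, 2] + 1e-3
  expect_error(vectorizePairs(asym), "symmetric")
})

test_that("feature datasets are deterministic, scale-invariant and tidy", {
  cohort <- simulateCohort(smallCohortConfig(seed = 31))
  ds <- buildFeatureDataset(cohort$manifest, cohort$series)
  expect_s4_class(ds, "ConnectivityDataset")
  expect_equal(dim(ds), c(16 * 15 / 2, 36))
  expect_equal(sum(groupLabels(ds) == 1L), 14)

  # bit-identical on rebuild
  ds2 <- buildFeatureDataset(cohort$manifest, cohort$series)
  expect_identical(featureMatrix(ds), featureMatrix(ds2))

  # positive rescaling of a subject's series leaves its features unchanged
  scaled <- cohort$series
  scaled[[3]] <- roiTimeSeries(scaled[[3]]@values * 7.5, tr = scaled[[3]]@tr)
  ds3 <- buildFeatureDataset(cohort$manifest, scaled)
  expect_equal(featureMatrix(ds3)[3, ], featureMatrix(ds)[3, ],
               tolerance = 1e-10)

  # permuting the manifest permutes feature rows only
  perm <- sample(nrow(cohort$manifest))
  dsP <- buildFeatureDataset(cohort$manifest[perm, ], cohort$series)
  expect_identical(featureMatrix(dsP),
                   featureMatrix(ds)[perm, ])

  # with all processing off, the chain collapses to Fisher-z correlations
  dsRaw <- buildFeatureDataset(cohort$manifest, cohort$series,
    detrend = FALSE, globalSignal = FALSE, filter = FALSE)
  direct <- vectorizePairs(cor(cohort$series[[1]]@values))
  expect_equal(featureMatrix(dsRaw)[1, ], direct, tolerance = 1e-12)

  # ROI-count mismatch is a named error
  broken <- cohort$series
  broken[[2]] <- roiTimeSeries(broken[[2]]@values[, 1:10], tr = 2)
  expect_error(buildFeatureDataset(cohort$manifest, broken), "mismatch")
})
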