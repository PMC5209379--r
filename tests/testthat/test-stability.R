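# Subsample validation: prefiltering, AUC, splitting, center covariates,
# the full loop and its aggregations.

test_that("prefiltering keeps exactly the label-correlated features", {
  withr::local_seed(20)
  y <- rep(c(1, 0), c(53, 118))
  X <- cbind(match = y + 0, noise = rnorm(171), flat = rep(1, 171))
  keep <- prefilterFeatures(X, y, threshold = 0.35)
  expect_identical(keep, 1L)           # |r| = 1 kept, noise and flat out

  # threshold zero retains every non-constant feature
  keep0 <- prefilterFeatures(X, y, threshold = 0)
  expect_identical(keep0, c(1L, 2L))

  # a feature independent of the label is excluded at n = 171
  expect_false(2L %in% prefilterFeatures(X, y, 0.35))
  expect_error(prefilterFeatures(X, rep(1, 171)), "both classes")
})

test_that("rank AUC equals trapezoidal ROC integration", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)

  toy <- list(scores = c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1),
              labels = c(1, 0, 1, 1, 0, 0))
  expect_equal(rocAuc(toy$scores, toy$labels),
               trapezoidAuc(toy$scores, toy$labels))

  withr::local_seed(21)
  for (k in 1:25) {
    n <- sample(6:30, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
    scores <- round(runif(n), 2)       # induce ties
    expect_equal(rocAuc(scores, labels), trapezoidAuc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
})

test_that("stratified subsampling reproduces the cohort arithmetic", {
  y <- rep(c(1L, 0L), c(53, 118))
  sp <- splitTrainTest(y, 2 / 3, seed = 9)
  expect_length(sp$train, 114)         # round(2/3*53) + round(2/3*118)
  expect_equal(sum(y[sp$train]), 35)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))

  # even per-class halves at fraction 0.5
  y2 <- rep(c(1L, 0L), c(20, 30))
  sp2 <- splitTrainTest(y2, 0.5, seed = 1)
  expect_length(sp2$train, 25)
  expect_equal(sum(y2[sp2$train]), 10)

  # determinism
  expect_identical(splitTrainTest(y, seed = 7), splitTrainTest(y, seed = 7))
  expect_error(splitTrainTest(rep(c(1L, 0L), c(2, 50)), 0.9, seed = 1),
               "empty")
})

test_that("center covariates are dummy-coded against the first site", {
  sites <- rep(c("siteA", "siteB", "siteC", "siteD"), times = c(4, 3, 2, 3))
  d <- addCenterCovariates(sites)
  expect_equal(dim(d), c(12, 3))
  expect_equal(colnames(d), c("center_siteB", "center_siteC",
                              "center_siteD"))
  expect_true(all(d[1:4, ] == 0))      # reference site rows are all zero
  expect_error(addCenterCovariates(rep("one", 5)), "2 sites")

  # forced covariates can be nonzero in the null-penalty regime
  withr::local_seed(22)
  X <- cbind(matrix(rnorm(200 * 3), 200, 3), dummy = rbinom(200, 1, 0.5))
  y <- rbinom(200, 1, plogis(1.5 * X[, 4] - 0.5))
  pf <- c(1, 1, 1, 0)
  lmax <- lambdaMax(X, y, 0.5, pf)
  fit <- fitElasticNet(X, y, 0.5, lmax * 1.01, penaltyFactors = pf)
  expect_identical(unname(stdCoefs(fit)[1:3]), c(0, 0, 0))
  expect_gt(abs(fit@coefficients[[4]]), 0.1)
})

test_that("the stability loop is deterministic and internally consistent", {
  ds <- smallFeatureDataset(seed = 55)
  cfg <- stabilityConfig(nIterations = 12, cvFolds = 5, cvRepeats = 2,
                         seed = 4)
  res <- runStability(ds, cfg)
  res2 <- runStability(ds, cfg)
  expect_identical(perIteration(res), perIteration(res2))
  expect_identical(res@selectionFrequencyTable, res2@selectionFrequencyTable)

  # consensus monotonicity in the threshold
  sf <- selectionFrequency(res, consensusThreshold = 0.5)
  sfStrict <- selectionFrequency(res, consensusThreshold = 1.0)
  expect_true(all(sfStrict$consensus$enet %in% sf$consensus$enet))
  expect_true(all(sfStrict$consensus$stepwise %in% sf$consensus$stepwise))

  # frequencies are selection counts over completed iterations
  counts <- tabulate(unlist(res@selectedEnet), nbins = nrow(ds))
  expect_equal(res@selectionFrequencyTable$enet, counts / 12)
  expect_true(all(perIteration(res)$aucEnet >= 0 &
                  perIteration(res)$aucEnet <= 1))
})

test_that("model fitting never sees held-out labels", {
  ds <- smallFeatureDataset(seed = 56)
  X <- featureMatrix(ds)
  y <- groupLabels(ds)
  cfg <- stabilityConfig(cvFolds = 5, cvRepeats = 2, seed = 8)
  sp <- splitTrainTest(y, 2 / 3, seed = 99)

  fit1 <- fitStabilityIteration(X, y, NULL, sp$train, cfg, cvSeed = 17)
  yCorrupt <- y
  yCorrupt[sp$test] <- 1L - yCorrupt[sp$test]
  fit2 <- fitStabilityIteration(X, yCorrupt, NULL, sp$train, cfg,
                                cvSeed = 17)
  expect_identical(fit1$selectedEnet, fit2$selectedEnet)
  expect_identical(fit1$selectedStepwise, fit2$selectedStepwise)
  expect_identical(fit1$enet@coefficients, fit2$enet@coefficients)
  expect_identical(fit1$stepwise@coefficients, fit2$stepwise@coefficients)
  expect_identical(fit1$lambdaSel@optimal, fit2$lambdaSel@optimal)
})

test_that("AUC summaries use empirical means and percentile intervals", {
  mk <- function(aucE, aucS) data.frame(iteration = seq_along(aucE),
    splitSeed = 1L, aucEnet = aucE, aucStepwise = aucS, lambda = 0.1,
    nPrefiltered = 5L, nSelectedEnet = 3L, nSelectedStepwise = 2L,
    vifMedianStepwise = 1, skipped = FALSE)

  # a constant AUC sequence has a zero-width interval
  s <- ConnStab:::summarizeAucTable(mk(rep(0.8, 50), rep(0.6, 50)))
  expect_equal(s$mean, c(0.8, 0.6))
  expect_equal(s$upper - s$lower, c(0, 0))

  # uniform draws approach the nominal 2.5/97.5 percentiles
  withr::local_seed(23)
  u <- runif(1e5)
  s2 <- ConnStab:::summarizeAucTable(mk(u, u))
  expect_lt(abs(s2$lower[1] - 0.025), 0.01)
  expect_lt(abs(s2$upper[1] - 0.975), 0.01)

  # invariant to iteration order
  perm <- sample(1e5)
  s3 <- ConnStab:::summarizeAucTable(mk(u[perm], u[perm]))
  expect_equal(s2$mean, s3$mean)
  expect_equal(s2$lower, s3$lower)
})

test_that("selection frequency is plain counting arithmetic", {
  sel <- c(replicate(6, c(1L, 4L), simplify = FALSE),
           replicate(4, 4L, simplify = FALSE))
  freq <- ConnStab:::selectionFrequencyVector(sel, rep(FALSE, 10), 6)
  expect_equal(freq, c(0.6, 0, 0, 1.0, 0, 0))

  # skipped iterations are excluded from the denominator
  freq2 <- ConnStab:::selectionFrequencyVector(c(sel, list(NULL)),
    c(rep(FALSE, 10), TRUE), 6)
  expect_equal(freq2[1], 0.6)
})

test_that("a null-effect cohort yields chance-level discrimination", {
  cohort <- simulateCohort(smallCohortConfig(seed = 60, nAffected = 0L))
  ds <- buildFeatureDataset(cohort$manifest, cohort$series, filter = FALSE)
  cfg <- stabilityConfig(nIterations = 30, cvFolds = 5, cvRepeats = 2,
                         seed = 10)
  res <- runStability(ds, cfg)
  s <- summarizeAuc(res, minIterations = 30)
  expect_gt(s$mean[s$model == "enet"], 0.35)
  expect_lt(s$mean[s$model == "enet"], 0.65)
  expect_gt(s$mean[s$model == "stepwise"], 0.35)
  expect_lt(s$mean[s$model == "stepwise"], 0.65)
})
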