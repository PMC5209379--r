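# Elastic-net penalized logistic regression: null-model regime, MLE limit,
# grid-search optimality, grouping of duplicated predictors, lambda grid
# and cross-validated lambda selection.

test_that("lambda at or above lambda_max yields the exact null model", {
  d <- randomLogisticData(120, c(1, -0.5, 0), seed = 1)
  lmax <- lambdaMax(d$X, d$y, alpha = 0.5)
  fit <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = lmax * 1.0001)
  expect_identical(unname(stdCoefs(fit)), c(0, 0, 0))
  ybar <- mean(d$y)
  expect_equal(fit@intercept, log(ybar / (1 - ybar)), tolerance = 1e-10)
  expect_equal(fit@nNonzero, 0L)

  # first grid value is lambda_max: still the null model
  grid <- lambdaGrid(d$X, d$y, alpha = 0.5)
  fit1 <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = grid[1])
  expect_equal(fit1@nNonzero, 0L)
})

test_that("the unpenalized limit recovers the maximum-likelihood fit", {
  d <- randomLogisticData(200, c(0.8, -0.6, 0.3), seed = 2)
  mle <- fitLogisticMle(d$X, d$y)
  fit0 <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = 0)
  expect_equal(unname(fit0@coefficients), unname(mle$coefficients),
               tolerance = 1e-4)
  expect_equal(fit0@intercept, mle$intercept, tolerance = 1e-4)
})

test_that("solutions are optimal against a dense objective grid", {
  d <- randomLogisticData(80, c(1, -1, 0.5), seed = 3)
  lam <- 0.08
  fit <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = lam)
  b <- stdCoefs(fit)
  obj <- enetObjectiveOracle(d$X, d$y, 0.5, lam, fit@intercept +
    sum(fit@coefficients * fit@center), b)   # intercept on std scale
  for (d1 in seq(-0.02, 0.02, by = 0.005))
    for (d2 in seq(-0.02, 0.02, by = 0.005))
      for (d3 in seq(-0.02, 0.02, by = 0.005)) {
        cand <- b + c(d1, d2, d3)
        objCand <- enetObjectiveOracle(d$X, d$y, 0.5, lam, fit@intercept +
          sum(fit@coefficients * fit@center), cand)
        expect_gte(objCand, obj - 1e-9)
      }
})

test_that("duplicated predictors are selected as a group", {
  d <- randomLogisticData(150, c(1.2), seed = 4)
  X <- cbind(a = d$X[, 1], b = d$X[, 1], c = rnorm(150))
  # tight tolerance: the duplicate-difference direction is the slowest
  # coordinate-descent mode, so convergence must be pushed further than
  # the default working tolerance to exhibit the exact grouping limit
  fit <- fitElasticNet(X, d$y, alpha = 0.5, lambda = 0.05, tol = 1e-13)
  expect_gt(abs(fit@coefficients[["a"]]), 0)
  expect_equal(fit@coefficients[["a"]], fit@coefficients[["b"]],
               tolerance = 1e-4)
})

test_that("subgradient stationarity holds across random problems", {
  for (s in 1:10) {
    p <- sample(2:6, 1)
    d <- randomLogisticData(60 + 10 * s, rnorm(p), seed = 100 + s)
    lam <- runif(1, 0.01, 0.3)
    a <- runif(1, 0.1, 1)
    fit <- fitElasticNet(d$X, d$y, alpha = a, lambda = lam)
    kkt <- enetKKT(fit, d$X, d$y, tol = 1e-4)
    expect_true(kkt$ok)
  }
})

test_that("the solver agrees with an independent reference implementation", {
  skip_if_not_installed("glmnet")
  d <- randomLogisticData(150, c(1, -0.7, 0.4, 0, 0), seed = 5)
  lam <- c(0.1, 0.03, 0.01)
  fits <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = lam)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.5,
                      lambda = lam, thresh = 1e-12, standardize = TRUE)
  for (k in seq_along(lam)) {
    expect_equal(unname(fits[[k]]@coefficients),
                 as.numeric(g$beta[, k]), tolerance = 2e-3)
    expect_equal(fits[[k]]@intercept, g$a0[[k]], tolerance = 2e-3)
  }
})

test_that("elastic-net objective is non-decreasing in lambda", {
  d <- randomLogisticData(100, c(0.9, -0.4), seed = 6)
  grid <- lambdaGrid(d$X, d$y, 0.5, nLambda = 25)
  fits <- fitElasticNet(d$X, d$y, 0.5, grid)
  objs <- vapply(fits, function(f) f@objectiveValue, numeric(1))
  expect_true(all(diff(rev(objs)) >= -1e-8))  # ascending lambda order
})

test_that("warm-started paths equal independent cold fits", {
  d <- randomLogisticData(90, c(1, 0.5, -0.5), seed = 7)
  grid <- lambdaGrid(d$X, d$y, 0.5, nLambda = 20)
  warm <- fitElasticNet(d$X, d$y, 0.5, grid)
  for (k in c(3, 10, 17)) {
    cold <- fitElasticNet(d$X, d$y, 0.5, grid[k])
    expect_equal(warm[[k]]@objectiveValue, cold@objectiveValue,
                 tolerance = 1e-6)
  }
})

test_that("ridge and lasso limits match independent solvers", {
  d <- randomLogisticData(120, c(0.8, -0.5, 0.3), seed = 8)
  lam <- 0.05

  # alpha = 0: smooth objective, check against a quasi-Newton minimizer
  ridge <- fitElasticNet(d$X, d$y, alpha = 0, lambda = lam)
  obj <- function(par) enetObjectiveOracle(d$X, d$y, 0, lam, par[1],
                                           par[2:4])
  opt <- optim(c(0, 0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(stdCoefs(ridge)), opt$par[2:4], tolerance = 1e-4)

  # alpha = 1: nonsmooth, check against an independent proximal-gradient
  # solver on the standardized objective
  lasso <- fitElasticNet(d$X, d$y, alpha = 1, lambda = lam)
  n <- nrow(d$X)
  ctr <- colMeans(d$X)
  scl <- sqrt(colSums(sweep(d$X, 2, ctr)^2) / n)
  Xs <- sweep(sweep(d$X, 2, ctr), 2, scl, "/")
  b <- c(0, 0, 0); b0 <- 0; step <- 1
  for (it in 1:20000) {
    eta <- b0 + Xs %*% b
    mu <- 1 / (1 + exp(-eta))
    gb <- -crossprod(Xs, d$y - mu) / n
    g0 <- -mean(d$y - mu)
    bn <- b - step * gb
    bn <- sign(bn) * pmax(abs(bn) - step * lam, 0)
    b0n <- b0 - step * g0
    if (max(abs(bn - b), abs(b0n - b0)) < 1e-12) break
    b <- as.numeric(bn); b0 <- b0n
  }
  expect_equal(unname(stdCoefs(lasso)), b, tolerance = 1e-4)
})

test_that("lambda grids are log-spaced from the null-model entry point", {
  d <- randomLogisticData(100, c(1, -1), seed = 9)
  grid <- lambdaGrid(d$X, d$y, alpha = 0.5, nLambda = 100)
  expect_length(grid, 100)
  expect_true(all(diff(grid) < 0))
  ratios <- grid[-1] / grid[-length(grid)]
  expect_lt(max(abs(ratios - ratios[1])), 1e-10)
  expect_equal(grid[1], lambdaMax(d$X, d$y, 0.5), tolerance = 1e-12)
  expect_equal(grid[100], grid[1] * 1e-4, tolerance = 1e-10)
})

test_that("cross-validated lambda selection is reproducible and sane", {
  d <- randomLogisticData(20, c(2, 0, 0), seed = 10)
  # leave-one-out, single repeat: exact reproducibility under a fixed seed
  s1 <- cvSelectLambda(d$X, d$y, folds = 20, repeats = 1, seed = 3,
                       nLambda = 30)
  s2 <- cvSelectLambda(d$X, d$y, folds = 20, repeats = 1, seed = 3,
                       nLambda = 30)
  expect_identical(s1@perRepeatBest, s2@perRepeatBest)
  expect_equal(s1@optimal, mean(s1@perRepeatBest))
  expect_true(s1@optimal >= min(s1@grid) && s1@optimal <= max(s1@grid))

  # pure noise drives lambda to the heavily regularized upper half of the
  # grid; strong signal pulls it below the grid midpoint and below the
  # matched noise optimum
  noiseHits <- signalHits <- pairedHits <- logical(20)
  for (s in 1:20) {
    withr::local_seed(200 + s)
    Xn <- matrix(rnorm(60 * 5), 60, 5)
    yn <- rbinom(60, 1, 0.5)
    if (length(unique(yn)) < 2) yn[1] <- 1 - yn[1]
    seln <- cvSelectLambda(Xn, yn, folds = 5, repeats = 1, seed = s,
                           nLambda = 30)
    mid <- exp(mean(log(range(seln@grid))))   # median grid position
    noiseHits[s] <- seln@perRepeatBest[1] >= mid

    Xs <- matrix(rnorm(60 * 5), 60, 5)
    ys <- rbinom(60, 1, plogis(3 * Xs[, 1]))
    if (length(unique(ys)) < 2) ys[1] <- 1 - ys[1]
    sels <- cvSelectLambda(Xs, ys, folds = 5, repeats = 1, seed = s,
                           nLambda = 30)
    mids <- mean(range(sels@grid))
    signalHits[s] <- sels@perRepeatBest[1] < mids
    pairedHits[s] <- sels@perRepeatBest[1] < seln@perRepeatBest[1]
  }
  expect_gte(mean(noiseHits), 0.8)
  expect_gte(mean(signalHits), 0.8)
  expect_gte(mean(pairedHits), 0.8)
})
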