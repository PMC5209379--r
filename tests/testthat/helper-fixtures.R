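# Shared fixtures, all generated in code.

# Small multi-site cohort for pipeline-level tests.
smallCohortConfig <- function(seed = 42L, nAffected = 6L) {
  simulationConfig(nRoi = 16L, nBlocks = 4L, nAd = 14L, nControl = 22L,
                   nSites = 2L, siteFractions = c(0.5, 0.5),
                   nTimepoints = c(80L, 60L), nAffected = nAffected,
                   seed = seed)
}

smallFeatureDataset <- function(seed = 42L, ...) {
  cohort <- simulateCohort(smallCohortConfig(seed = seed))
  buildFeatureDataset(cohort$manifest, cohort$series, ...)
}

# Random logistic-regression problem with known coefficients.
randomLogisticData <- function(n, beta, seed, intercept = 0) {
  withr::local_seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  y <- rbinom(n, 1, plogis(intercept + as.numeric(X %*% beta)))
  list(X = X, y = y)
}

# Directly assembled connectivity dataset (bypasses the simulator) with a
# feature matrix supplied by the caller: z is subjects x pairs.
datasetFromFeatures <- function(z, labels, sites, nRoi) {
  stopifnot(ncol(z) == nRoi * (nRoi - 1) / 2)
  manifest <- data.frame(subject_id = sprintf("s%03d", seq_len(nrow(z))),
                         group = as.integer(labels), site = sites,
                         stringsAsFactors = FALSE)
  connectivityDataset(t(z), manifest, paste0("ROI", seq_len(nRoi)))
}

# Independent trapezoidal ROC integration (threshold sweep), used as the
# oracle for the rank-based AUC.
trapezoidAuc <- function(scores, labels) {
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Independent elastic-net objective evaluation (standardized scale), used
# by grid-search and limit-case oracles.
enetObjectiveOracle <- function(X, y, alpha, lambda, b0, beta,
                                pf = rep(1, ncol(X))) {
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colSums(sweep(X, 2, ctr)^2) / n)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  eta <- b0 + as.numeric(Xs %*% beta)
  ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                             log1p(exp(eta))))
  -ll / n + lambda * sum(pf * ((1 - alpha) / 2 * beta^2 + alpha * abs(beta)))
}

# Standardized-scale coefficients of an ElasticNetFit.
stdCoefs <- function(fit) fit@coefficients * fit@scale
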