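# Subsample validation: repeated stratified 2/3-train / 1/3-test splits,
# per-split prefiltering, model fitting and held-out AUC for both learners,
# and aggregation into selection-frequency profiles and consensus networks.

#' Prefilter features by point-biserial correlation with diagnosis
#'
#' Retains exactly the features whose Pearson correlation with the 0/1
#' label exceeds the threshold in absolute value. Constant features are
#' never retained. The returned set may be empty.
#'
#' @param features subjects-by-features numeric matrix.
#' @param labels 0/1 diagnosis vector (both classes present).
#' @param threshold |r| cutoff (default 0.35).
#' @return Integer vector of retained column indices.
#' @export
prefilterFeatures <- function(features, labels, threshold = 0.35) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  r <- suppressWarnings(as.numeric(stats::cor(features, labels)))
  which(!is.na(r) & abs(r) > threshold)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' random positive (AD) scores above a random negative, counting ties as
#' one half.
#'
#' @param scores numeric risk scores (higher = more AD-like).
#' @param labels 0/1 vector, 1 = positive class.
#' @return AUC in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test subsample split
#'
#' Draws, without replacement, a training subsample of the given fraction
#' (rounded within each class under stratification); the remainder is the
#' test set. Train and test are disjoint and exhaustive.
#'
#' @param labels 0/1 vector defining the strata.
#' @param trainFraction training proportion (default 2/3).
#' @param seed integer seed.
#' @param stratified stratify by label (default TRUE).
#' @return List with integer vectors \code{train} and \code{test}.
#' @export
splitTrainTest <- function(labels, trainFraction = 2 / 3, seed = 1L,
                           stratified = TRUE) {
  labels <- as.integer(labels)
  n <- length(labels)
  train <- withSeed(seed, {
    if (stratified) {
      unlist(lapply(unique(labels), function(cls) {
        idx <- which(labels == cls)
        k <- round(trainFraction * length(idx))
        if (k < 1L || k >= length(idx))
          stop("trainFraction leaves class ", cls,
               " empty in train or test")
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      k <- round(trainFraction * n)
      sample.int(n, k)
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  if (length(unique(labels[train])) < 2L || length(unique(labels[test])) < 2L)
    stop("split leaves a class empty; use stratified = TRUE or adjust ",
         "trainFraction")
  list(train = train, test = test)
}

#' Dummy-coded center covariates
#'
#' Builds \code{n_sites - 1} treatment-coded dummy columns (reference =
#' first site in sorted order). In the elastic net they enter with penalty
#' factor 0 (forced, unpenalized); in the stepwise search they are forced
#' non-droppable terms; they are exempt from prefiltering.
#'
#' @param x a \linkS4class{ConnectivityDataset} or a character vector of
#'   site labels.
#' @return Matrix of 0/1 dummies with columns \code{center_<site>}.
#' @export
addCenterCovariates <- function(x) {
  sites <- if (is(x, "ConnectivityDataset")) siteLabels(x) else as.character(x)
  lev <- sort(unique(sites))
  if (length(lev) < 2L) stop("need at least 2 sites for center covariates")
  d <- vapply(lev[-1L], function(s) as.numeric(sites == s),
              numeric(length(sites)))
  colnames(d) <- paste0("center_", lev[-1L])
  d
}

# One subsample iteration: prefilter on training rows, fit both models on
# training rows only, score on the held-out rows. Test labels are used
# exclusively for the held-out AUC.
#' Fit both models for one subsample iteration
#'
#' Exposed mainly so the training stage can be audited and parallelized:
#' everything that touches model fitting sees only \code{trainIdx} rows.
#'
#' @param features subjects-by-pairs matrix.
#' @param labels 0/1 diagnosis vector.
#' @param centers optional dummy matrix from
#'   \code{\link{addCenterCovariates}} (NULL = no center covariates).
#' @param trainIdx integer training row indices.
#' @param config a \linkS4class{StabilityConfig}.
#' @param cvSeed seed for the lambda-selection CV.
#' @return List with selected pair indices, held-out-ready fits, chosen
#'   lambda, prefiltered count and the per-model training summaries.
#' @export
fitStabilityIteration <- function(features, labels, centers, trainIdx,
                                  config, cvSeed = 1L) {
  trainX <- features[trainIdx, , drop = FALSE]
  trainY <- labels[trainIdx]
  keep <- prefilterFeatures(trainX, trainY, config@prefilterThreshold)
  pairNames <- colnames(features)[keep]
  nCenter <- if (is.null(centers)) 0L else ncol(centers)
  design <- cbind(trainX[, keep, drop = FALSE],
                  if (nCenter) centers[trainIdx, , drop = FALSE])
  centerNames <- if (nCenter) colnames(centers) else character()

  enet <- NULL; lambdaSel <- NULL
  if (length(keep)) {
    pf <- c(rep(1, length(keep)), rep(0, nCenter))
    lambdaSel <- cvSelectLambda(design, trainY, alpha = config@alpha,
      penaltyFactors = pf, folds = config@cvFolds,
      repeats = config@cvRepeats, seed = cvSeed, nLambda = config@nLambda,
      minRatio = config@lambdaMinRatio)
    enet <- fitElasticNet(design, trainY, alpha = config@alpha,
                          lambda = lambdaSel@optimal, penaltyFactors = pf)
  }
  selEnet <- if (is.null(enet)) integer()
    else keep[enet@coefficients[seq_along(keep)] != 0]

  step <- NULL
  if (length(keep)) {
    step <- fitStepwise(design, trainY, candidateTerms = pairNames,
                        forcedTerms = centerNames)
  }
  selStep <- if (is.null(step)) integer()
    else keep[match(step@selectedTerms, pairNames)]

  vifMedian <- NA_real_
  stepCols <- c(if (!is.null(step)) step@selectedTerms, centerNames)
  if (length(stepCols) >= 2L) {
    vifMedian <- tryCatch(
      median(computeVif(design[, stepCols, drop = FALSE])),
      error = function(e) NA_real_)
  }

  list(keep = keep, enet = enet, lambdaSel = lambdaSel, stepwise = step,
       selectedEnet = selEnet, selectedStepwise = selStep,
       vifMedian = vifMedian, centerNames = centerNames)
}

scoreIteration <- function(itfit, features, labels, centers, testIdx) {
  testY <- labels[testIdx]
  testDesign <- cbind(features[testIdx, itfit$keep, drop = FALSE],
                      if (length(itfit$centerNames))
                        centers[testIdx, , drop = FALSE])
  aucE <- if (is.null(itfit$enet)) 0.5
    else rocAuc(predictEnet(itfit$enet, testDesign), testY)
  aucS <- if (is.null(itfit$stepwise)) 0.5
    else rocAuc(predictStepwise(itfit$stepwise, testDesign), testY)
  list(aucEnet = aucE, aucStepwise = aucS)
}

#' Run the full subsample-validation comparison
#'
#' Per iteration: draw a stratified training subsample; prefilter candidate
#' pairs on the training rows only; select lambda by repeated CV and fit
#' the elastic net; run the AIC-stepwise search; score both on the held-out
#' rows by rank AUC. Aggregates per-pair selection frequencies, consensus
#' networks at the configured threshold, AUC summaries and model sizes.
#' Iteration failures are recorded and skipped; the run aborts if more than
#' 10 percent of iterations skip.
#'
#' @param dataset a \linkS4class{ConnectivityDataset}.
#' @param config a \linkS4class{StabilityConfig}.
#' @param verbose log progress every 10 iterations.
#' @return A \linkS4class{StabilityResults}.
#' @export
runStability <- function(dataset, config = stabilityConfig(),
                         verbose = FALSE) {
  validObject(config)
  features <- featureMatrix(dataset)
  labels <- groupLabels(dataset)
  centers <- if (config@includeCenters) addCenterCovariates(dataset) else NULL
  B <- config@nIterations
  seeds <- deriveSeeds(config@seed, 2L * B)

  rows <- vector("list", B)
  selE <- vector("list", B)
  selS <- vector("list", B)
  for (b in seq_len(B)) {
    split <- splitTrainTest(labels, config@trainFraction,
                            seed = seeds[2L * b - 1L],
                            stratified = config@stratified)
    rec <- tryCatch({
      itfit <- fitStabilityIteration(features, labels, centers,
                                     split$train, config,
                                     cvSeed = seeds[2L * b])
      sc <- scoreIteration(itfit, features, labels, centers, split$test)
      list(df = data.frame(iteration = b, splitSeed = seeds[2L * b - 1L],
             aucEnet = sc$aucEnet, aucStepwise = sc$aucStepwise,
             lambda = if (is.null(itfit$lambdaSel)) NA_real_
                      else itfit$lambdaSel@optimal,
             nPrefiltered = length(itfit$keep),
             nSelectedEnet = length(itfit$selectedEnet),
             nSelectedStepwise = length(itfit$selectedStepwise),
             vifMedianStepwise = itfit$vifMedian, skipped = FALSE),
           e = itfit$selectedEnet, s = itfit$selectedStepwise)
    }, error = function(err) {
      warning("iteration ", b, " skipped: ", conditionMessage(err))
      list(df = data.frame(iteration = b, splitSeed = seeds[2L * b - 1L],
             aucEnet = NA_real_, aucStepwise = NA_real_, lambda = NA_real_,
             nPrefiltered = NA_integer_, nSelectedEnet = NA_integer_,
             nSelectedStepwise = NA_integer_,
             vifMedianStepwise = NA_real_, skipped = TRUE),
           e = NULL, s = NULL)
    })
    rows[[b]] <- rec$df
    selE[[b]] <- rec$e
    selS[[b]] <- rec$s
    if (verbose && b %% 10L == 0L)
      message("iteration ", b, "/", B)
  }
  perIteration <- do.call(rbind, rows)
  nSkipped <- sum(perIteration$skipped)
  if (nSkipped > 0.1 * B)
    stop(nSkipped, " of ", B, " iterations failed (> 10%); aborting")

  nPairs <- ncol(features)
  freqE <- selectionFrequencyVector(selE, perIteration$skipped, nPairs)
  freqS <- selectionFrequencyVector(selS, perIteration$skipped, nPairs)
  pt <- pairInfo(dataset)
  freqTable <- data.frame(pair = seq_len(nPairs),
                          name = colnames(features),
                          enet = freqE, stepwise = freqS)
  thr <- config@consensusThreshold
  consensus <- list(enet = which(freqE >= thr), stepwise = which(freqS >= thr))
  aucSum <- summarizeAucTable(perIteration)
  sizes <- c(enet = median(perIteration$nSelectedEnet, na.rm = TRUE),
             stepwise = median(perIteration$nSelectedStepwise, na.rm = TRUE))
  new("StabilityResults", perIteration = perIteration, selectedEnet = selE,
      selectedStepwise = selS, selectionFrequencyTable = freqTable,
      aucSummary = aucSum, consensus = consensus, medianModelSize = sizes,
      config = config,
      pairIndex = pt)
}

selectionFrequencyVector <- function(selected, skipped, nPairs) {
  done <- which(!skipped)
  if (!length(done)) return(rep(NA_real_, nPairs))
  counts <- tabulate(unlist(selected[done], use.names = FALSE), nPairs)
  counts / length(done)
}

summarizeAucTable <- function(perIteration) {
  do.call(rbind, lapply(c("enet", "stepwise"), function(m) {
    a <- perIteration[[if (m == "enet") "aucEnet" else "aucStepwise"]]
    a <- a[!is.na(a)]
    data.frame(model = m, mean = mean(a),
               lower = as.numeric(quantile(a, 0.025, type = 7)),
               upper = as.numeric(quantile(a, 0.975, type = 7)),
               n = length(a), stringsAsFactors = FALSE)
  }))
}

#' Selection frequencies and consensus networks
#'
#' Frequency = (iterations selecting the pair) / (completed iterations);
#' the consensus network is every pair at or above the threshold.
#'
#' @param results a \linkS4class{StabilityResults}.
#' @param consensusThreshold frequency cutoff (defaults to the run's
#'   configured value).
#' @return List with \code{frequency} (data.frame: pair, name, enet,
#'   stepwise) and \code{consensus} (list of pair-index vectors per model).
#' @export
selectionFrequency <- function(results,
    consensusThreshold = results@config@consensusThreshold) {
  stopifnot(is(results, "StabilityResults"))
  f <- results@selectionFrequencyTable
  if (!nrow(f) || all(is.na(f$enet))) stop("no completed iterations")
  list(frequency = f,
       consensus = list(enet = which(f$enet >= consensusThreshold),
                        stepwise = which(f$stepwise >= consensusThreshold)))
}

#' Summarize held-out AUC distributions
#'
#' Empirical mean and 2.5/97.5 percentile interval of the per-iteration
#' held-out AUCs, per model.
#'
#' @param results a \linkS4class{StabilityResults}.
#' @param minIterations minimum completed iterations required for a stable
#'   percentile interval (default 40).
#' @return data.frame with columns model, mean, lower, upper, n.
#' @export
summarizeAuc <- function(results, minIterations = 40L) {
  stopifnot(is(results, "StabilityResults"))
  done <- sum(!results@perIteration$skipped)
  if (done < minIterations)
    stop("only ", done, " completed iterations; need >= ", minIterations)
  summarizeAucTable(results@perIteration)
}

#' Accessor: per-iteration records of a stability run
#' @param results a \linkS4class{StabilityResults}.
#' @return data.frame, one row per subsample iteration.
#' @export
perIteration <- function(results) results@perIteration

#' Accessor: consensus pair sets of a stability run
#' @param results a \linkS4class{StabilityResults}.
#' @param model \code{"enet"} or \code{"stepwise"}.
#' @return Integer vector of pair indices.
#' @export
consensusFeatures <- function(results, model = c("enet", "stepwise")) {
  results@consensus[[match.arg(model)]]
}
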