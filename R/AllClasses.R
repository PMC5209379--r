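#' ROI time-series container
#'
#' Holds one subject's extracted ROI signals: a time-by-region numeric
#' matrix together with the sampling interval (TR, seconds) and ordered
#' region labels.
#'
#' @slot values numeric matrix, rows = time points, columns = ROIs.
#' @slot tr sampling interval in seconds.
#' @slot roiLabels character vector, one label per column.
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(values = "matrix", tr = "numeric", roiLabels = "character"))

setValidity("RoiTimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 2L) return("need at least 2 time points")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite, no NA")
  if (length(object@tr) != 1L || object@tr <= 0) return("tr must be a single positive number")
  if (length(object@roiLabels) != ncol(v)) return("one roiLabel per column required")
  if (anyDuplicated(object@roiLabels)) return("roiLabels must be unique")
  TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param values time-by-ROI numeric matrix.
#' @param tr sampling interval in seconds.
#' @param roiLabels optional region labels (defaults to column names or
#'   \code{ROI1..ROIR}).
#' @return A \linkS4class{RoiTimeSeries}.
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(40), 20, 2), tr = 2)
#' @export
roiTimeSeries <- function(values, tr, roiLabels = NULL) {
  values <- as.matrix(values)
  if (is.null(roiLabels)) {
    roiLabels <- colnames(values)
    if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(ncol(values)))
  }
  colnames(values) <- roiLabels
  new("RoiTimeSeries", values = values, tr = as.numeric(tr),
      roiLabels = as.character(roiLabels))
}

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries:", nrow(object@values), "time points x",
      ncol(object@values), "ROIs, TR =", object@tr, "s\n")
})

#' Synthetic cohort simulation settings
#'
#' Cohort-shape defaults mirror the multicenter study the package models:
#' 53 AD cases vs 118 controls over 4 scanner sites with 194/114/174/114
#' usable volumes, 84 ROIs hence 3486 pairwise features. Block structure,
#' affected-pair count and effect size parameterize the planted group
#' difference the analysis is meant to recover.
#'
#' @slot nRoi,nAd,nControl,nSites,nBlocks,nAffected integer counts.
#' @slot siteFractions per-site assignment proportions (sum 1).
#' @slot nTimepoints per-site usable time-point counts.
#' @slot rhoWithin,rhoBetween block correlation levels.
#' @slot effectDelta correlation reduction on affected pairs in the AD group.
#' @slot arCoef lag-1 autoregressive coefficient of the noise process.
#' @slot siteScaleSd s.d. of the per-site log variance multiplier.
#' @slot seed master seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nRoi = "integer", nAd = "integer", nControl = "integer",
    nSites = "integer", siteFractions = "numeric", nTimepoints = "integer",
    nBlocks = "integer", rhoWithin = "numeric", rhoBetween = "numeric",
    nAffected = "integer", effectDelta = "numeric", arCoef = "numeric",
    siteScaleSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nRoi < 2L) msg <- c(msg, "nRoi must be >= 2")
  if (object@nAd < 1L || object@nControl < 1L) msg <- c(msg, "need both groups")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (length(object@siteFractions) != object@nSites)
    msg <- c(msg, "siteFractions length must equal nSites")
  if (abs(sum(object@siteFractions) - 1) > 1e-9)
    msg <- c(msg, "siteFractions must sum to 1 (tolerance 1e-9)")
  if (any(object@siteFractions < 0)) msg <- c(msg, "siteFractions must be >= 0")
  if (length(object@nTimepoints) != object@nSites)
    msg <- c(msg, "nTimepoints length must equal nSites")
  if (any(object@nTimepoints < 2L)) msg <- c(msg, "nTimepoints must be >= 2")
  if (object@nBlocks < 1L || object@nBlocks > object@nRoi)
    msg <- c(msg, "nBlocks must be in [1, nRoi]")
  npair <- object@nRoi * (object@nRoi - 1L) / 2L
  if (object@nAffected < 0L || object@nAffected > npair)
    msg <- c(msg, "nAffected must be in [0, nRoi*(nRoi-1)/2]")
  if (!(object@rhoBetween >= 0 && object@rhoBetween < object@rhoWithin &&
        object@rhoWithin < 1))
    msg <- c(msg, "need 0 <= rhoBetween < rhoWithin < 1")
  if (object@arCoef < 0 || object@arCoef >= 1) msg <- c(msg, "arCoef must be in [0,1)")
  if (object@siteScaleSd < 0) msg <- c(msg, "siteScaleSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nRoi,nAd,nControl,nSites,nBlocks,nAffected counts; see class docs.
#' @param siteFractions proportions summing to 1 (default equal).
#' @param nTimepoints per-site usable volumes (default c(194, 114, 174, 114),
#'   recycled/truncated to \code{nSites}).
#' @param rhoWithin,rhoBetween within-/between-block target correlations.
#' @param effectDelta correlation reduction on affected pairs (AD group).
#' @param arCoef temporal AR(1) coefficient in [0,1).
#' @param siteScaleSd s.d. of per-site log variance multipliers.
#' @param seed master integer seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nRoi = 84L, nAd = 53L, nControl = 118L,
    nSites = 4L, siteFractions = rep(1 / nSites, nSites),
    nTimepoints = c(194L, 114L, 174L, 114L), nBlocks = 12L,
    rhoWithin = 0.5, rhoBetween = 0.1, nAffected = 20L, effectDelta = 0.25,
    arCoef = 0.3, siteScaleSd = 0.1, seed = 1L) {
  nTimepoints <- rep_len(as.integer(nTimepoints), nSites)
  new("SimulationConfig", nRoi = as.integer(nRoi), nAd = as.integer(nAd),
      nControl = as.integer(nControl), nSites = as.integer(nSites),
      siteFractions = as.numeric(siteFractions), nTimepoints = nTimepoints,
      nBlocks = as.integer(nBlocks), rhoWithin = rhoWithin,
      rhoBetween = rhoBetween, nAffected = as.integer(nAffected),
      effectDelta = effectDelta, arCoef = arCoef, siteScaleSd = siteScaleSd,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nAd, "AD /", object@nControl, "controls,",
      object@nRoi, "ROIs,", object@nSites, "sites,", object@nBlocks,
      "blocks,", object@nAffected, "affected pairs (delta r =",
      object@effectDelta, "), seed", object@seed, "\n")
})

#' Planted ground truth of a synthetic cohort
#'
#' @slot affectedPairs integer indices (canonical pair order) of the pairs
#'   whose correlation is reduced in the AD group.
#' @slot controlCorr,adCorr target ROI correlation matrices after
#'   positive-definite repair.
#' @slot siteMultipliers named per-site variance factors.
#' @slot blocks integer block assignment per ROI.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(affectedPairs = "integer", controlCorr = "matrix",
    adCorr = "matrix", siteMultipliers = "numeric", blocks = "integer"))

setValidity("GroundTruth", function(object) {
  C <- object@controlCorr; A <- object@adCorr
  if (!isSymmetric(unname(C), tol = 1e-8) || !isSymmetric(unname(A), tol = 1e-8))
    return("correlation matrices must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8 || max(abs(diag(A) - 1)) > 1e-8)
    return("correlation matrices must have unit diagonal")
  npair <- nrow(C) * (nrow(C) - 1L) / 2L
  if (length(object@affectedPairs) &&
      (min(object@affectedPairs) < 1L || max(object@affectedPairs) > npair))
    return("affectedPairs out of range")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@controlCorr), "ROIs,",
      length(object@affectedPairs), "affected pairs,",
      length(object@siteMultipliers), "site multipliers\n")
})

#' Accessor: planted affected pair indices
#' @param object a \linkS4class{GroundTruth}.
#' @return integer vector of canonical pair indices.
#' @export
affectedPairs <- function(object) object@affectedPairs

#' Subject-by-feature connectivity dataset
#'
#' A \linkS4class{SummarizedExperiment} holding the Fisher-z pairwise
#' connectivity features: assay \code{"z"} is pairs-by-subjects, rowData
#' carries the canonical pair index (\code{roi1}, \code{roi2} and labels)
#' and colData the subject manifest (\code{group}: 0 control / 1 AD;
#' \code{site}; demographics).
#'
#' @exportClass ConnectivityDataset
setClass("ConnectivityDataset", contains = "SummarizedExperiment")

setValidity("ConnectivityDataset", function(object) {
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    return("assay 'z' required")
  cd <- colData(object)
  if (!all(c("group", "site") %in% colnames(cd)))
    return("colData must contain 'group' and 'site'")
  if (!all(cd$group %in% c(0L, 1L)))
    return("group must be coded 0 (control) / 1 (AD)")
  rd <- rowData(object)
  if (!all(c("roi1", "roi2") %in% colnames(rd)))
    return("rowData must contain pair columns 'roi1' and 'roi2'")
  if (any(rd$roi1 >= rd$roi2)) return("pair index must satisfy roi1 < roi2")
  TRUE
})

#' Elastic-net penalized logistic fit
#'
#' @slot alpha L1/L2 mixing parameter.
#' @slot lambda penalty strength.
#' @slot intercept,coefficients estimates on the original predictor scale.
#' @slot penaltyFactors per-feature penalty multipliers (0 = forced).
#' @slot center,scale standardization used internally.
#' @slot nNonzero number of nonzero penalized coefficients.
#' @slot converged solver flag.
#' @slot objectiveValue penalized objective at the solution.
#' @exportClass ElasticNetFit
setClass("ElasticNetFit",
  representation(alpha = "numeric", lambda = "numeric", intercept = "numeric",
    coefficients = "numeric", penaltyFactors = "numeric", center = "numeric",
    scale = "numeric", nNonzero = "integer", converged = "logical",
    objectiveValue = "numeric"))

setMethod("show", "ElasticNetFit", function(object) {
  cat("ElasticNetFit: alpha =", object@alpha, "lambda =",
      signif(object@lambda, 4), "|", object@nNonzero,
      "nonzero of", length(object@coefficients), "features; objective =",
      signif(object@objectiveValue, 6), "\n")
})

#' AIC-stepwise logistic fit
#'
#' @slot selectedTerms names of retained candidate terms.
#' @slot coefficients named vector, intercept first.
#' @slot aic final AIC.
#' @slot loglik maximized log-likelihood of the final model.
#' @slot trace data.frame of (step, action, term, aic).
#' @slot forcedTerms terms never eligible for dropping.
#' @exportClass StepwiseFit
setClass("StepwiseFit",
  representation(selectedTerms = "character", coefficients = "numeric",
    aic = "numeric", loglik = "numeric", trace = "data.frame",
    forcedTerms = "character"))

setMethod("show", "StepwiseFit", function(object) {
  cat("StepwiseFit:", length(object@selectedTerms), "terms, AIC =",
      signif(object@aic, 6), "(", nrow(object@trace), "search steps )\n")
})

#' Cross-validated lambda selection
#'
#' @slot grid descending lambda grid.
#' @slot perRepeatBest deviance-minimizing lambda per CV repeat.
#' @slot optimal mean of the per-repeat minimizers.
#' @slot folds,repeats,seed CV settings.
#' @exportClass LambdaSelection
setClass("LambdaSelection",
  representation(grid = "numeric", perRepeatBest = "numeric",
    optimal = "numeric", folds = "integer", repeats = "integer",
    seed = "integer"))

setValidity("LambdaSelection", function(object) {
  if (object@optimal < min(object@grid) - 1e-12 ||
      object@optimal > max(object@grid) + 1e-12)
    return("optimal lambda must lie within the grid range")
  TRUE
})

setMethod("show", "LambdaSelection", function(object) {
  cat("LambdaSelection:", length(object@grid), "grid values,",
      object@repeats, "repeats x", object@folds, "folds; optimal lambda =",
      signif(object@optimal, 4), "\n")
})

#' Subsample-validation settings
#'
#' Defaults follow the published design: 1000 draws of a stratified 2/3
#' training subsample, candidate features prefiltered at |r| > 0.35 against
#' diagnosis in the training data, consensus networks at 50% selection
#' frequency, elastic-net alpha 0.5 with lambda chosen by repeated
#' cross-validated deviance.
#'
#' @slot nIterations number of subsample draws.
#' @slot trainFraction training proportion per draw.
#' @slot prefilterThreshold point-biserial |r| cutoff.
#' @slot consensusThreshold selection-frequency cutoff for consensus sets.
#' @slot includeCenters force site dummy covariates into both models.
#' @slot stratified stratify the subsample by diagnosis.
#' @slot alpha elastic-net mixing parameter.
#' @slot cvFolds,cvRepeats lambda-selection cross-validation settings.
#' @slot nLambda,lambdaMinRatio lambda grid shape.
#' @slot seed master seed.
#' @exportClass StabilityConfig
setClass("StabilityConfig",
  representation(nIterations = "integer", trainFraction = "numeric",
    prefilterThreshold = "numeric", consensusThreshold = "numeric",
    includeCenters = "logical", stratified = "logical", alpha = "numeric",
    cvFolds = "integer", cvRepeats = "integer", nLambda = "integer",
    lambdaMinRatio = "numeric", seed = "integer"))

setValidity("StabilityConfig", function(object) {
  msg <- character()
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0,1)")
  if (object@prefilterThreshold < 0 || object@prefilterThreshold >= 1)
    msg <- c(msg, "prefilterThreshold must be in [0,1)")
  if (object@consensusThreshold <= 0 || object@consensusThreshold > 1)
    msg <- c(msg, "consensusThreshold must be in (0,1]")
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must be in [0,1]")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StabilityConfig
#'
#' @param nIterations subsample draws (1000 in the full design; use ~100
#'   for a reduced profile).
#' @param trainFraction training proportion (default 2/3).
#' @param prefilterThreshold |r| cutoff for candidate features (default 0.35).
#' @param consensusThreshold consensus frequency cutoff (default 0.5).
#' @param includeCenters force site dummies into both models.
#' @param stratified stratify subsamples by diagnosis.
#' @param alpha elastic-net mixing (default 0.5).
#' @param cvFolds,cvRepeats repeated CV shape for lambda selection
#'   (default 10 x 100; \code{cvFolds = 100, cvRepeats = 1} is the
#'   literal 100-fold variant).
#' @param nLambda,lambdaMinRatio lambda grid shape.
#' @param seed master integer seed.
#' @return A validated \linkS4class{StabilityConfig}.
#' @export
stabilityConfig <- function(nIterations = 1000L, trainFraction = 2 / 3,
    prefilterThreshold = 0.35, consensusThreshold = 0.5,
    includeCenters = FALSE, stratified = TRUE, alpha = 0.5,
    cvFolds = 10L, cvRepeats = 100L, nLambda = 100L, lambdaMinRatio = 1e-4,
    seed = 1L) {
  new("StabilityConfig", nIterations = as.integer(nIterations),
      trainFraction = trainFraction, prefilterThreshold = prefilterThreshold,
      consensusThreshold = consensusThreshold,
      includeCenters = includeCenters, stratified = stratified, alpha = alpha,
      cvFolds = as.integer(cvFolds), cvRepeats = as.integer(cvRepeats),
      nLambda = as.integer(nLambda), lambdaMinRatio = lambdaMinRatio,
      seed = as.integer(seed))
}

setMethod("show", "StabilityConfig", function(object) {
  cat("StabilityConfig:", object@nIterations, "iterations, train fraction",
      signif(object@trainFraction, 4), ", prefilter |r| >",
      object@prefilterThreshold, ", alpha =", object@alpha, ", CV",
      object@cvRepeats, "x", object@cvFolds, "folds, centers:",
      object@includeCenters, ", seed", object@seed, "\n")
})

#' Subsample-validation results
#'
#' @slot perIteration one row per subsample draw: held-out AUCs, chosen
#'   lambda, prefiltered feature count, selected-set sizes, skip flags.
#' @slot selectedEnet,selectedStepwise list of per-iteration selected pair
#'   index vectors.
#' @slot selectionFrequencyTable per-pair selection proportions per model.
#' @slot aucSummary per-model mean and 2.5/97.5 percentile interval.
#' @slot consensus list of consensus pair-index vectors per model.
#' @slot medianModelSize per-model median selected-feature count.
#' @slot config the \linkS4class{StabilityConfig} used.
#' @slot pairIndex data.frame mapping pair index to ROI labels.
#' @exportClass StabilityResults
setClass("StabilityResults",
  representation(perIteration = "data.frame", selectedEnet = "list",
    selectedStepwise = "list", selectionFrequencyTable = "data.frame",
    aucSummary = "data.frame", consensus = "list",
    medianModelSize = "numeric", config = "StabilityConfig",
    pairIndex = "data.frame"))

setValidity("StabilityResults", function(object) {
  f <- object@selectionFrequencyTable
  if (nrow(f)) {
    fr <- as.matrix(f[, c("enet", "stepwise")])
    if (any(fr < -1e-12 | fr > 1 + 1e-12)) return("frequencies must be in [0,1]")
  }
  a <- object@perIteration
  if (nrow(a)) {
    ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
    if (!ok(a$aucEnet) || !ok(a$aucStepwise)) return("AUCs must be in [0,1]")
  }
  TRUE
})

setMethod("show", "StabilityResults", function(object) {
  n <- nrow(object@perIteration)
  cat("StabilityResults:", n, "iterations\n")
  if (nrow(object@aucSummary)) {
    s <- object@aucSummary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-9s mean AUC %.3f [%.3f, %.3f], consensus %d pairs, median model size %s\n",
          s$model[i], s$mean[i], s$lower[i], s$upper[i],
          length(object@consensus[[s$model[i]]]),
          format(object@medianModelSize[s$model[i]])))
  }
})
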