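# Report assembly and configuration plumbing: one call from a feature
# dataset to a results bundle on disk, an alpha sweep (deviance-vs-lambda
# curves per mixing value), and a schema-checked run configuration.

#' Run the stability comparison and write a results bundle
#'
#' Executes \code{\link{runStability}} and writes, under \code{outDir}:
#' \code{per_iteration.tsv}, \code{summary.json} (AUC means and percentile
#' intervals, consensus sets, median model sizes, median stepwise VIF),
#' \code{selection_frequency.tsv} (pair label, elastic-net and stepwise
#' frequencies), \code{consensus.tsv} (consensus pairs with ROI labels and
#' frequencies), \code{frequency_curves.tsv} (per-model sorted frequency
#' curves) and \code{model_size_histogram.tsv}, plus the resolved
#' configuration (\code{config.json}) for bit-identical reruns.
#'
#' @param dataset a \linkS4class{ConnectivityDataset}.
#' @param config a \linkS4class{StabilityConfig}.
#' @param outDir output directory (created if missing).
#' @param verbose log progress.
#' @return The \linkS4class{StabilityResults}, invisibly.
#' @export
runAnalysis <- function(dataset, config = stabilityConfig(), outDir,
                        verbose = FALSE) {
  res <- runStability(dataset, config, verbose = verbose)
  writeResultsBundle(res, outDir)
  invisible(res)
}

configToList <- function(config) {
  sl <- methods::slotNames(class(config))
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

writeResultsBundle <- function(results, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(df,
    file.path(outDir, name), sep = "\t", row.names = FALSE, quote = FALSE)

  tsv(results@perIteration, "per_iteration.tsv")
  freq <- results@selectionFrequencyTable
  tsv(freq, "selection_frequency.tsv")

  consensusTable <- do.call(rbind, lapply(c("enet", "stepwise"), function(m) {
    idx <- results@consensus[[m]]
    if (!length(idx)) return(NULL)
    pi <- results@pairIndex[idx, , drop = FALSE]
    data.frame(model = m, frequency_pct = 100 * freq[[m]][idx],
               pair = freq$name[idx],
               label1 = pi$label1, label2 = pi$label2,
               stringsAsFactors = FALSE)
  }))
  if (is.null(consensusTable))
    consensusTable <- data.frame(model = character(),
      frequency_pct = numeric(), pair = character(),
      label1 = character(), label2 = character())
  consensusTable <- consensusTable[order(consensusTable$model,
                                         -consensusTable$frequency_pct), ]
  tsv(consensusTable, "consensus.tsv")

  curves <- do.call(rbind, lapply(c("enet", "stepwise"), function(m)
    data.frame(model = m, rank = seq_len(nrow(freq)),
               frequency = sort(freq[[m]], decreasing = TRUE))))
  tsv(curves, "frequency_curves.tsv")

  hist <- do.call(rbind, lapply(c("enet", "stepwise"), function(m) {
    sizes <- results@perIteration[[if (m == "enet") "nSelectedEnet"
                                   else "nSelectedStepwise"]]
    tab <- table(sizes[!is.na(sizes)])
    data.frame(model = m, n_features = as.integer(names(tab)),
               count = as.integer(tab))
  }))
  tsv(hist, "model_size_histogram.tsv")

  summary <- list(
    tool = "ConnStab", version = as.character(packageVersion("ConnStab")),
    auc = results@aucSummary,
    median_model_size = as.list(results@medianModelSize),
    median_vif_stepwise =
      median(results@perIteration$vifMedianStepwise, na.rm = TRUE),
    consensus = lapply(results@consensus, function(idx) freq$name[idx]),
    n_iterations = nrow(results@perIteration),
    n_skipped = sum(results@perIteration$skipped))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(configToList(results@config),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Cross-validated deviance curves over a grid of alpha values
#'
#' For each mixing value, computes the lambda grid and the mean
#' out-of-fold binomial deviance along the path (one repeat of stratified
#' k-fold CV), supporting the choice of alpha by minimum deviance.
#'
#' @param X design matrix (typically the prefiltered features).
#' @param y 0/1 response.
#' @param alphas mixing values to sweep (default 0, 0.1, ..., 1).
#' @param folds CV folds (default 10).
#' @param seed integer seed (same folds across alphas).
#' @param nLambda,minRatio grid shape.
#' @return data.frame with columns alpha, lambda, deviance, nNonzero.
#' @export
alphaSweep <- function(X, y, alphas = seq(0, 1, 0.1), folds = 10L,
                       seed = 1L, nLambda = 100L, minRatio = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  foldId <- withSeed(seed, {
    id <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  do.call(rbind, lapply(alphas, function(a) {
    aEff <- max(a, 1e-3)          # finite grid entry point for ridge
    grid <- lambdaGrid(X, y, aEff, nLambda = nLambda, minRatio = minRatio)
    dev <- numeric(length(grid))
    nnz <- numeric(length(grid))
    for (f in seq_len(folds)) {
      hold <- foldId == f
      fits <- fitElasticNet(X[!hold, , drop = FALSE], y[!hold], a, grid)
      for (l in seq_along(grid)) {
        mu <- pmin(pmax(predictEnet(fits[[l]], X[hold, , drop = FALSE]),
                        1e-10), 1 - 1e-10)
        dev[l] <- dev[l] -
          2 * sum(y[hold] * log(mu) + (1 - y[hold]) * log(1 - mu))
        nnz[l] <- nnz[l] + fits[[l]]@nNonzero / folds
      }
    }
    data.frame(alpha = a, lambda = grid, deviance = dev / n,
               nNonzero = nnz)
  }))
}

runConfigSchema <- list(
  schema_version = "1",
  simulation = names(formals(simulationConfig)),
  stability = names(formals(stabilityConfig)),
  connectivity = c("detrend", "globalSignal", "filter", "lowHz", "highHz"),
  output = c("dir"))

#' Read and validate a run configuration file
#'
#' YAML or JSON with nested sections \code{simulation}, \code{stability},
#' \code{connectivity} and \code{output}; unknown sections or keys are
#' rejected. Missing keys fall back to package defaults.
#'
#' @param path configuration file (.yaml/.yml/.json).
#' @return Named list of validated sections.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema_version", names(runConfigSchema)[-1L])
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (section in intersect(names(raw), names(runConfigSchema)[-1L])) {
    extra <- setdiff(names(raw[[section]]), runConfigSchema[[section]])
    if (length(extra)) stop("unknown key(s) in section '", section, "': ",
                            paste(extra, collapse = ", "))
  }
  raw
}
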