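# Bidirectional AIC-stepwise logistic regression. Starting from the full
# candidate model, each step evaluates every single-term drop (forced terms
# excluded) and every single-term add, moves to the neighbor with the
# lowest AIC when it strictly improves, and stops at a local AIC minimum.

#' Bidirectional AIC-stepwise logistic regression
#'
#' Greedy add/drop search over candidate terms weighted by the Akaike
#' information criterion, \eqn{AIC = -2\ell + 2(1 + k)}. Ties are broken
#' by preferring drops over adds, then the lowest candidate index. Forced
#' terms are present in every evaluated model and never droppable. A
#' candidate model whose likelihood fit fails is skipped with a warning.
#'
#' @param X design matrix whose columns are the candidate (and forced)
#'   terms; column names identify terms.
#' @param y 0/1 response.
#' @param candidateTerms character vector of searchable column names
#'   (default: all columns not forced).
#' @param forcedTerms character vector of always-included column names.
#' @param direction \code{"both"} (default), \code{"backward"} (drops
#'   only) or \code{"forward"} (starts from forced-only model, adds only).
#' @param maxSteps search-step ceiling (default 1000).
#' @param ridgeStabilizer passed to \code{\link{fitLogisticMle}}.
#' @param maxit IRLS iteration budget per candidate fit (default 50;
#'   separated candidate models stop here with the stabilized iterate,
#'   which is all the AIC comparison needs).
#' @return A \linkS4class{StepwiseFit}.
#' @export
fitStepwise <- function(X, y, candidateTerms = NULL, forcedTerms = character(),
                        direction = c("both", "backward", "forward"),
                        maxSteps = 1000L, ridgeStabilizer = 1e-8,
                        maxit = 50L) {
  direction <- match.arg(direction)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(candidateTerms))
    candidateTerms <- setdiff(colnames(X), forcedTerms)
  stopifnot(all(candidateTerms %in% colnames(X)),
            all(forcedTerms %in% colnames(X)))
  if (length(candidateTerms) < 1L) stop("need at least one candidate term")

  cache <- new.env(parent = emptyenv())
  evalModel <- function(terms) {
    key <- paste0("m:", paste(sort(terms), collapse = "\r"))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- tryCatch({
      fit <- fitLogisticMle(X[, terms, drop = FALSE], y,
                            ridgeStabilizer = ridgeStabilizer, maxit = maxit)
      list(aic = fit$aic, fit = fit)
    }, error = function(e) {
      warning("candidate model {", paste(terms, collapse = ", "),
              "} failed: ", conditionMessage(e))
      list(aic = Inf, fit = NULL)
    })
    cache[[key]] <- out
    out
  }

  current <- if (direction == "forward") forcedTerms
             else union(forcedTerms, candidateTerms)
  cur <- evalModel(current)
  trace <- data.frame(step = 0L, action = "start",
                      term = NA_character_, aic = cur$aic,
                      stringsAsFactors = FALSE)

  for (step in seq_len(maxSteps)) {
    droppable <- if (direction == "forward") character()
                 else setdiff(intersect(current, candidateTerms), forcedTerms)
    addable <- if (direction == "backward") character()
               else setdiff(candidateTerms, current)
    # candidate moves in tie-break order: drops first, each in column order
    moves <- rbind(
      if (length(droppable))
        data.frame(action = "drop", term = droppable,
                   ord = match(droppable, colnames(X))),
      if (length(addable))
        data.frame(action = "add", term = addable,
                   ord = match(addable, colnames(X))))
    if (is.null(moves) || nrow(moves) == 0L) break
    moves <- moves[order(moves$action == "add", moves$ord), , drop = FALSE]
    aics <- vapply(seq_len(nrow(moves)), function(m) {
      terms <- if (moves$action[m] == "drop") setdiff(current, moves$term[m])
               else c(current, moves$term[m])
      evalModel(terms)$aic
    }, numeric(1))
    bestm <- which.min(aics)      # first minimum respects the tie-break order
    if (!(aics[bestm] < cur$aic - 1e-10)) break
    current <- if (moves$action[bestm] == "drop")
      setdiff(current, moves$term[bestm]) else c(current, moves$term[bestm])
    cur <- evalModel(current)
    trace <- rbind(trace, data.frame(step = step, action = moves$action[bestm],
                                     term = moves$term[bestm], aic = cur$aic,
                                     stringsAsFactors = FALSE))
  }

  if (is.null(cur$fit)) stop("stepwise search ended on an unfittable model")
  selected <- intersect(colnames(X), current)   # column order
  cf <- c("(Intercept)" = cur$fit$intercept, cur$fit$coefficients)
  new("StepwiseFit",
      selectedTerms = setdiff(selected, forcedTerms),
      coefficients = cf, aic = cur$aic, loglik = cur$fit$loglik,
      trace = trace, forcedTerms = as.character(forcedTerms))
}

#' Class-probability predictions from a stepwise fit
#'
#' @param fit a \linkS4class{StepwiseFit}.
#' @param X design matrix containing the fit's columns.
#' @return Probabilities of the positive class.
#' @export
predictStepwise <- function(fit, X) {
  terms <- setdiff(names(fit@coefficients), "(Intercept)")
  eta <- fit@coefficients[["(Intercept)"]] +
    if (length(terms))
      as.numeric(as.matrix(X[, terms, drop = FALSE]) %*%
                 fit@coefficients[terms]) else 0
  1 / (1 + exp(-eta))
}
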