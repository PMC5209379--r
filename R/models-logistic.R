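# Maximum-likelihood logistic regression via IRLS with step-halving and a
# small ridge stabilizer (keeps separable fits finite). Base fitter for the
# stepwise search and for lambda = 0 checks of the penalized solver.

#' Fit a binomial logistic regression by IRLS
#'
#' Iteratively reweighted least squares with step-halving, at most
#' \code{maxit} iterations. A ridge stabilizer (default 1e-8, applied to
#' slope coefficients only) bounds the estimates under quasi-complete
#' separation; non-convergence is flagged and the last iterate returned.
#'
#' @param X numeric design matrix without intercept column (may have zero
#'   columns for an intercept-only model).
#' @param y 0/1 response containing both classes.
#' @param ridgeStabilizer ridge penalty on slopes (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100).
#' @param tol convergence tolerance on the objective change (default 1e-10).
#' @return List with \code{intercept}, \code{coefficients}, \code{loglik}
#'   (unpenalized, at the estimate), \code{converged}, \code{iterations},
#'   and \code{aic} = \eqn{-2\ell + 2(1 + p)}.
#' @examples
#' y <- rep(c(0, 1), c(30, 10))
#' fitLogisticMle(matrix(numeric(0), 40, 0), y)$intercept  # log(10/30)
#' @export
fitLogisticMle <- function(X, y, ridgeStabilizer = 1e-8, maxit = 100L,
                           tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (ncol(X) > 0L) {
    v <- apply(X, 2L, stats::sd)
    if (any(v == 0)) stop("constant column(s) in design: ",
                          paste(which(v == 0), collapse = ", "))
  }
  fit <- cpp_logistic_irls(X, y, ridgeStabilizer, as.integer(maxit), tol)
  cf <- as.numeric(fit$coefficients)
  names(cf) <- colnames(X)
  list(intercept = fit$intercept, coefficients = cf, loglik = fit$loglik,
       converged = fit$converged, iterations = fit$iterations,
       aic = -2 * fit$loglik + 2 * (1 + ncol(X)))
}

#' Class-probability predictions from a logistic fit
#'
#' @param fit result of \code{\link{fitLogisticMle}}.
#' @param X design matrix matching the fit.
#' @return Vector of probabilities of the positive class.
#' @export
predictLogistic <- function(fit, X) {
  eta <- fit$intercept +
    if (length(fit$coefficients)) as.matrix(X) %*% fit$coefficients else 0
  as.numeric(1 / (1 + exp(-eta)))
}
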