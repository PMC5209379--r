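# Variance inflation factor diagnostics for multicollinearity.

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from the OLS
#' regression of column j on all remaining columns plus an intercept.
#' Values above 5 are conventionally read as serious multicollinearity.
#' Near-singular designs are capped at 1e12.
#'
#' @param X numeric matrix with at least two columns and no zero-variance
#'   column.
#' @return Named vector of VIFs, all \eqn{\ge 1}.
#' @examples
#' computeVif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
computeVif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 columns")
  v <- apply(X, 2L, stats::sd)
  if (any(v == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  out <- vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    res <- qr.resid(qr(Zj), yj)
    r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) 1e12 else min(1 / (1 - r2), 1e12)
  }, numeric(1))
  names(out) <- colnames(X)
  pmax(out, 1)
}
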