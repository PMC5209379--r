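# Featurization: ROI time series -> Fisher-z pairwise connectivity vector.

#' Canonical pair index
#'
#' Row-major enumeration of the strict upper triangle: (1,2), (1,3), ...,
#' (1,R), (2,3), ..., (R-1,R). All feature vectors in the package share
#' this ordering.
#'
#' @param nRoi number of regions.
#' @param labels optional ROI labels.
#' @return data.frame with columns \code{pair} (index), \code{roi1},
#'   \code{roi2} (integer positions) and, when labels are given,
#'   \code{label1}, \code{label2} and a combined \code{name}
#'   (\code{"label1__label2"}).
#' @examples
#' pairIndexTable(4)
#' @export
pairIndexTable <- function(nRoi, labels = NULL) {
  nRoi <- as.integer(nRoi)
  i <- rep.int(seq_len(nRoi - 1L), times = (nRoi - 1L):1L)
  j <- unlist(lapply(seq_len(nRoi - 1L), function(k) (k + 1L):nRoi),
              use.names = FALSE)
  out <- data.frame(pair = seq_along(i), roi1 = i, roi2 = j)
  if (!is.null(labels)) {
    out$label1 <- labels[i]
    out$label2 <- labels[j]
    out$name <- paste0(out$label1, "__", out$label2)
  }
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Replaces each ROI column by its residual from an ordinary least-squares
#' fit on an intercept plus the supplied regressors (e.g. head-motion
#' parameters, global/WM/CSF mean signals, a linear trend). Rank-deficient
#' regressor sets are handled by dropping dependent columns with a warning.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param regressors numeric matrix, one row per time point; \code{NULL} or
#'   zero columns means intercept-only (column demeaning).
#' @return A \linkS4class{RoiTimeSeries} of residuals.
#' @export
nuisanceRegress <- function(ts, regressors = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  n <- nrow(ts@values)
  if (is.null(regressors)) regressors <- matrix(numeric(0), n, 0)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != n)
    stop("regressor rows (", nrow(regressors),
         ") must match time points (", n, ")")
  X <- cbind(1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("rank-deficient regressor matrix; dropping ",
            ncol(X) - qrX$rank, " dependent column(s)")
    qrX <- qr(X[, keep, drop = FALSE])
  }
  resid <- ts@values - qr.fitted(qrX, ts@values)
  roiTimeSeries(resid, tr = ts@tr, roiLabels = ts@roiLabels)
}

#' Ideal band-pass filter in the Fourier domain
#'
#' Zeroes every discrete Fourier coefficient whose frequency magnitude lies
#' outside \code{[lowHz, highHz]} (the DC term is always removed) and
#' inverse-transforms. The operator is an exact orthogonal projector: it is
#' idempotent and the output variance obeys Parseval's identity over the
#' retained frequency bins. Slow drifts below \code{lowHz} are suppressed
#' by the mask itself; explicit linear detrending is part of the nuisance
#' regression step of \code{\link{buildFeatureDataset}}.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param lowHz,highHz pass-band edges in Hz (defaults 0.01 and 0.1);
#'   \code{highHz} must stay below the Nyquist frequency \code{1/(2 TR)}.
#' @return The filtered \linkS4class{RoiTimeSeries}.
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.1) {
  stopifnot(is(ts, "RoiTimeSeries"))
  tr <- ts@tr
  nyquist <- 1 / (2 * tr)
  if (!(lowHz > 0 && lowHz < highHz))
    stop("need 0 < lowHz < highHz")
  if (highHz >= nyquist)
    stop("highHz (", highHz, " Hz) must be below the Nyquist frequency (",
         signif(nyquist, 4), " Hz) for TR = ", tr, " s")
  n <- nrow(ts@values)
  freq <- (seq_len(n) - 1L) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)       # fold to [0, Nyquist]
  keep <- freq >= lowHz & freq <= highHz  # excludes DC (freq 0)
  out <- apply(ts@values, 2L, function(x) {
    xf <- stats::fft(x)
    xf[!keep] <- 0 + 0i
    Re(stats::fft(xf, inverse = TRUE)) / n
  })
  roiTimeSeries(out, tr = tr, roiLabels = ts@roiLabels)
}

#' Pearson correlation matrix of ROI time series
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  v <- apply(ts@values, 2L, stats::sd)
  if (any(v == 0))
    stop("zero-variance ROI(s): ",
         paste(ts@roiLabels[v == 0], collapse = ", "))
  stats::cor(ts@values)
}

#' Fisher z-transform of a correlation coefficient
#'
#' \eqn{z = 0.5 \ln[(1+r)/(1-r)]}, with \eqn{r} clipped to
#' \eqn{\pm(1 - 10^{-7})} so degenerate correlations stay finite.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return Transformed value(s).
#' @examples
#' fisherZ(0.5)  # 0.5 * log(3) = 0.5493
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Vectorize a correlation matrix into Fisher-z pair features
#'
#' Extracts the strict upper triangle in the canonical row-major pair order
#' of \code{\link{pairIndexTable}} and applies \code{\link{fisherZ}}.
#'
#' @param mat symmetric correlation matrix (asymmetry beyond 1e-8 is an
#'   error).
#' @return Named numeric vector of length \code{R(R-1)/2}.
#' @export
vectorizePairs <- function(mat) {
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8))
    stop("input matrix is not symmetric (tolerance 1e-8)")
  R <- nrow(mat)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(R))
  # row-major strict upper triangle == column-major strict lower triangle
  z <- fisherZ(t(mat)[lower.tri(mat)])
  pt <- pairIndexTable(R, labels)
  names(z) <- pt$name
  z
}

#' Build the subject-by-pair connectivity feature dataset
#'
#' Chains, per subject: nuisance regression (optionally including a linear
#' trend and the mean-across-ROIs global signal) -> ideal band-pass filter
#' -> Pearson correlation -> Fisher-z vectorization, and assembles the
#' results into a \linkS4class{ConnectivityDataset}.
#'
#' @param manifest data.frame with at least \code{subject_id}, \code{group}
#'   (0/1) and \code{site}; extra columns are carried into colData.
#' @param series named list of \linkS4class{RoiTimeSeries}, one per
#'   manifest row.
#' @param nuisance optional named list of per-subject regressor matrices.
#' @param detrend include a linear time covariate among the nuisance
#'   regressors (default TRUE).
#' @param globalSignal include the mean-across-ROIs time course as a
#'   regressor, standing in for the global signal (default TRUE).
#' @param filter apply the band-pass filter (default TRUE).
#' @param lowHz,highHz pass band (defaults 0.01-0.1 Hz).
#' @param verbose log one line per subject to standard error.
#' @return A \linkS4class{ConnectivityDataset}; processing options are
#'   stored in \code{metadata()}.
#' @export
buildFeatureDataset <- function(manifest, series, nuisance = NULL,
    detrend = TRUE, globalSignal = TRUE, filter = TRUE,
    lowHz = 0.01, highHz = 0.1, verbose = FALSE) {
  stopifnot(all(c("subject_id", "group", "site") %in% names(manifest)))
  ids <- manifest$subject_id
  if (!all(ids %in% names(series)))
    stop("missing time series for subject(s): ",
         paste(setdiff(ids, names(series)), collapse = ", "))
  first <- series[[ids[1L]]]
  R <- ncol(first@values)
  labels <- first@roiLabels
  rows <- lapply(ids, function(id) {
    ts <- series[[id]]
    if (ncol(ts@values) != R)
      stop("ROI count mismatch for subject ", id, ": ", ncol(ts@values),
           " vs ", R)
    n <- nrow(ts@values)
    reg <- matrix(numeric(0), n, 0)
    if (detrend) reg <- cbind(reg, trend = seq_len(n))
    if (globalSignal) reg <- cbind(reg, global = rowMeans(ts@values))
    if (!is.null(nuisance) && !is.null(nuisance[[id]]))
      reg <- cbind(reg, as.matrix(nuisance[[id]]))
    ts <- nuisanceRegress(ts, if (ncol(reg)) reg else NULL)
    if (filter) ts <- bandpassFilter(ts, lowHz, highHz)
    if (verbose)
      message("featurized ", id, " (", n, " x ", R, ")")
    vectorizePairs(correlationMatrix(ts))
  })
  z <- do.call(cbind, rows)   # pairs x subjects
  colnames(z) <- ids
  connectivityDataset(z, manifest, labels,
    options = list(detrend = detrend, globalSignal = globalSignal,
                   filter = filter, lowHz = lowHz, highHz = highHz))
}
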