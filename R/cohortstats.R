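# Demographic group comparisons: chi-square for sex distribution, pooled t
# for age/education, Mann-Whitney U for neuropsychological scores. Thin,
# contract-checked wrappers around the standard stats tests.

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Without continuity correction by default, so the statistic equals
#' \eqn{\sum (O-E)^2/E} over the four cells with expectations from the
#' margins (reproducing printed group-by-sex comparisons); a corrected
#' variant is available by flag.
#'
#' @param counts 2x2 matrix of non-negative counts (rows = group,
#'   columns = category); all margins must be positive.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return List with \code{statistic}, \code{df} (= 1) and \code{p}.
#' @examples
#' chiSquare2x2(matrix(c(31, 22, 61, 57), 2, byrow = TRUE))
#' @export
chiSquare2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  ht <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample Student t-test
#'
#' Pooled-variance t statistic with \eqn{df = n_1 + n_2 - 2} by default
#' (Welch by flag), two-sided p-value.
#'
#' @param x,y numeric samples (each n >= 2); NAs are dropped.
#' @param pooled use the pooled-variance statistic (default TRUE).
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @export
twoSampleT <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (stats::var(c(x - mean(x), y - mean(y))) == 0)
    stop("zero pooled variance")
  ht <- t.test(x, y, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Midrank-tie U statistic (number of (x, y) pairs with x > y, ties as one
#' half) with tie-corrected normal approximation, two-sided.
#'
#' @param x,y numeric samples; NAs are dropped.
#' @return List with \code{statistic} (U for x over y) and \code{p}.
#' @export
mannWhitneyU <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Demographic comparison table for a cohort manifest
#'
#' Reproduces the usual baseline table: sex by chi-square, age and years
#' of education by pooled t-test, neuropsychological scores (e.g. MMSE) by
#' Mann-Whitney U. Degrees of freedom reflect the non-missing data
#' actually supplied.
#'
#' @param manifest data.frame with \code{group} (0/1) and any of
#'   \code{sex}, \code{age}, \code{education}, \code{mmse}.
#' @return data.frame with one row per comparison: variable, test,
#'   statistic, df, p.
#' @export
demographicsTable <- function(manifest) {
  stopifnot("group" %in% names(manifest))
  g <- as.integer(manifest$group)
  rows <- list()
  addRow <- function(variable, test, statistic, df, p)
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable,
      test = test, statistic = statistic, df = df, p = p,
      stringsAsFactors = FALSE)
  if ("sex" %in% names(manifest)) {
    tab <- table(factor(g, levels = c(1L, 0L)), manifest$sex)
    ct <- chiSquare2x2(as.matrix(tab))
    addRow("sex", "chi-square", ct$statistic, ct$df, ct$p)
  }
  for (v in intersect(c("age", "education"), names(manifest))) {
    tt <- twoSampleT(manifest[[v]][g == 1L], manifest[[v]][g == 0L])
    addRow(v, "t (pooled)", tt$statistic, tt$df, tt$p)
  }
  for (v in intersect(c("mmse", "moca"), names(manifest))) {
    xs <- manifest[[v]][g == 1L]; ys <- manifest[[v]][g == 0L]
    if (all(is.na(xs)) || all(is.na(ys))) next
    mw <- mannWhitneyU(xs, ys)
    addRow(v, "Mann-Whitney U", mw$statistic, NA_real_, mw$p)
  }
  do.call(rbind, rows)
}
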