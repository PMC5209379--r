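# Synthetic multi-site cohort generator. Produces ROI time series whose
# population correlation structure carries (i) block collinearity mirroring
# grouping of pairwise features by functional network, (ii) a localized
# correlation reduction in the AD group on a known set of within-block
# pairs, and (iii) per-site variance perturbations. Ground truth is kept
# for recovery experiments.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed streams derived from one master seed, so that
# ground truth, cohort assembly and per-subject simulation draw from
# independent, order-insensitive streams.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

blockAssignment <- function(nRoi, nBlocks) {
  sort(rep_len(seq_len(nBlocks), nRoi))
}

# Eigenvalue clipping at a small floor, then rescaling to unit diagonal.
repairPositiveDefinite <- function(mat, floor = 1e-4) {
  es <- eigen(mat, symmetric = TRUE)
  vals <- pmax(es$values, floor)
  rep <- es$vectors %*% (vals * t(es$vectors))
  d <- sqrt(diag(rep))
  rep <- rep / tcrossprod(d)
  diag(rep) <- 1
  (rep + t(rep)) / 2
}

#' Build target group correlation matrices with planted AD effects
#'
#' Constructs a block-structured control correlation matrix
#' (\code{rhoWithin} inside each network block, \code{rhoBetween} across
#' blocks), then subtracts \code{effectDelta} on \code{nAffected} randomly
#' chosen within-block pairs to form the AD matrix. Both matrices are
#' repaired to positive definiteness by eigenvalue clipping (floor 1e-4)
#' and rescaled to unit diagonal; per-site variance multipliers are drawn
#' as \code{exp(N(0, siteScaleSd^2))}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' gt <- makeGroupCorrelations(simulationConfig(nRoi = 12, nBlocks = 3,
#'   nAffected = 4, seed = 7))
#' affectedPairs(gt)
#' @export
makeGroupCorrelations <- function(config) {
  validObject(config)
  seeds <- deriveSeeds(config@seed, 5L)
  R <- config@nRoi
  blocks <- blockAssignment(R, config@nBlocks)
  C <- outer(blocks, blocks,
             function(a, b) ifelse(a == b, config@rhoWithin, config@rhoBetween))
  diag(C) <- 1
  rownames(C) <- colnames(C) <- paste0("ROI", seq_len(R))

  pairs <- pairIndexTable(R)
  within <- which(blocks[pairs$roi1] == blocks[pairs$roi2])
  if (config@nAffected > length(within))
    stop("nAffected exceeds the number of within-block pairs (",
         length(within), ")")
  affected <- if (config@nAffected > 0L)
    sort(withSeed(seeds[1L], sample(within, config@nAffected)))
  else integer()

  A <- C
  for (k in affected) {
    i <- pairs$roi1[k]; j <- pairs$roi2[k]
    A[i, j] <- A[j, i] <- A[i, j] - config@effectDelta
  }

  Cr <- repairPositiveDefinite(C)
  Ar <- repairPositiveDefinite(A)
  drift <- max(abs(Cr - C), abs(Ar - A))
  if (drift > 0.05)
    stop("positive-definite repair distorts target correlations by ",
         signif(drift, 3), " (> 0.05); effect size and block structure are ",
         "incompatible")

  mult <- withSeed(seeds[2L],
                   exp(stats::rnorm(config@nSites, 0, config@siteScaleSd)))
  names(mult) <- paste0("site", seq_len(config@nSites))

  new("GroundTruth", affectedPairs = as.integer(affected), controlCorr = Cr,
      adCorr = Ar, siteMultipliers = mult, blocks = as.integer(blocks))
}

#' Simulate one subject's ROI time series
#'
#' Draws a stationary Gaussian AR(1) process
#' \eqn{x_t = \phi x_{t-1} + \sqrt{1-\phi^2}\, e_t} with innovations
#' \eqn{e_t \sim N(0, m_s \Sigma_g)}, where \eqn{\Sigma_g} is the group
#' correlation matrix and \eqn{m_s} the site variance multiplier, so the
#' marginal covariance at every time point equals \eqn{m_s \Sigma_g}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param group \code{"AD"} or \code{"control"}.
#' @param site site label (one of \code{names(truth@siteMultipliers)}) or index.
#' @param nTimepoints number of rows to simulate.
#' @param seed integer seed for this subject.
#' @param arCoef AR(1) coefficient in [0,1).
#' @param tr sampling interval in seconds attached to the output.
#' @return A \linkS4class{RoiTimeSeries}.
#' @export
simulateSubject <- function(truth, group = c("AD", "control"), site = 1L,
                            nTimepoints, seed, arCoef = 0.3, tr = 2) {
  group <- match.arg(group)
  nTimepoints <- as.integer(nTimepoints)
  if (nTimepoints < 1L) stop("nTimepoints must be positive")
  sig <- if (group == "AD") truth@adCorr else truth@controlCorr
  mult <- if (is.character(site)) truth@siteMultipliers[[site]]
          else truth@siteMultipliers[[as.integer(site)]]
  R <- nrow(sig)
  cholS <- chol(sig * mult)
  phi <- arCoef
  x <- withSeed(seed, {
    innov <- matrix(stats::rnorm(nTimepoints * R), nTimepoints, R) %*% cholS
    out <- matrix(0, nTimepoints, R)
    out[1L, ] <- innov[1L, ]
    if (nTimepoints > 1L) {
      s <- sqrt(1 - phi^2)
      for (t in 2L:nTimepoints) out[t, ] <- phi * out[t - 1L, ] + s * innov[t, ]
    }
    out
  })
  colnames(x) <- rownames(sig)
  roiTimeSeries(x, tr = tr)
}

# Largest-remainder apportionment of n units to fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a full multi-site cohort
#'
#' Generates \code{nAd + nControl} subjects assigned to sites by
#' largest-remainder apportionment of \code{siteFractions} (shuffled within
#' the cohort), with each site's time-point count and sampling interval,
#' per-subject derived seeds, and demographics drawn to match the cohort
#' the defaults emulate (sex ratio 31/53 vs 61/118, age 72.4 (8.8) vs
#' 70.4 (6.2) years, education 11.4 (2.1) vs 13.6 (3.1) years, MMSE
#' 22.5 (4.4) vs 28.8 (1.0)).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param trBySite per-site sampling intervals in seconds.
#' @return A list with elements \code{manifest} (data.frame), \code{series}
#'   (named list of \linkS4class{RoiTimeSeries}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' cohort <- simulateCohort(simulationConfig(nRoi = 10, nBlocks = 2,
#'   nAd = 5, nControl = 8, nAffected = 3, nTimepoints = 40, seed = 1))
#' table(cohort$manifest$group)
#' @export
simulateCohort <- function(config, trBySite = c(2.61, 3, 2.58, 3)) {
  validObject(config)
  seeds <- deriveSeeds(config@seed, 5L)
  truth <- makeGroupCorrelations(config)
  n <- config@nAd + config@nControl
  trBySite <- rep_len(trBySite, config@nSites)

  siteCounts <- apportion(n, config@siteFractions)
  sites <- withSeed(seeds[3L],
                    sample(rep.int(seq_len(config@nSites), siteCounts)))
  group <- c(rep(1L, config@nAd), rep(0L, config@nControl))

  demo <- withSeed(seeds[4L], {
    sex <- ifelse(stats::runif(n) < ifelse(group == 1L, 31 / 53, 61 / 118),
                  "F", "M")
    age <- ifelse(group == 1L, stats::rnorm(n, 72.4, 8.8),
                  stats::rnorm(n, 70.4, 6.2))
    edu <- ifelse(group == 1L, stats::rnorm(n, 11.4, 2.1),
                  stats::rnorm(n, 13.6, 3.1))
    mmse <- ifelse(group == 1L, stats::rnorm(n, 22.5, 4.4),
                   stats::rnorm(n, 28.8, 1.0))
    data.frame(sex = sex, age = round(age, 1), education = round(edu, 1),
               mmse = round(pmin(mmse, 30), 1))
  })

  subjSeeds <- withSeed(seeds[5L], sample.int(.Machine$integer.max - 1L, n))
  ids <- sprintf("sub%03d", seq_len(n))
  manifest <- data.frame(subject_id = ids,
                         group = group,
                         site = paste0("site", sites),
                         tr = trBySite[sites],
                         n_timepoints = config@nTimepoints[sites],
                         seed = subjSeeds,
                         demo,
                         stringsAsFactors = FALSE)

  series <- vector("list", n)
  names(series) <- ids
  for (k in seq_len(n)) {
    series[[k]] <- simulateSubject(truth,
      group = if (group[k] == 1L) "AD" else "control",
      site = sites[k], nTimepoints = config@nTimepoints[sites[k]],
      seed = subjSeeds[k], arCoef = config@arCoef, tr = trBySite[sites[k]])
  }
  list(manifest = manifest, series = series, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes \code{manifest.csv}, one headerless time-series CSV per subject
#' (T rows by R columns) and \code{ground_truth.json} (affected pair
#' indices, site multipliers, block assignment).
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (id in cohort$manifest$subject_id) {
    utils::write.table(cohort$series[[id]]@values,
      file.path(dir, paste0(id, ".csv")), sep = ",", row.names = FALSE,
      col.names = FALSE)
  }
  gt <- list(affected_pairs = cohort$truth@affectedPairs,
             site_multipliers = as.list(cohort$truth@siteMultipliers),
             blocks = cohort$truth@blocks,
             n_roi = nrow(cohort$truth@controlCorr))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir directory containing \code{manifest.csv} and per-subject CSVs.
#' @return A list with \code{manifest} and \code{series} (list of
#'   \linkS4class{RoiTimeSeries}).
#' @export
readCohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  series <- lapply(seq_len(nrow(manifest)), function(k) {
    f <- file.path(dir, paste0(manifest$subject_id[k], ".csv"))
    if (!file.exists(f)) stop("missing time-series file for subject ",
                              manifest$subject_id[k])
    m <- as.matrix(read.csv(f, header = FALSE))
    dimnames(m) <- NULL
    tr <- if ("tr" %in% names(manifest)) manifest$tr[k] else 2
    roiTimeSeries(m, tr = tr)
  })
  names(series) <- manifest$subject_id
  list(manifest = manifest, series = series)
}
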