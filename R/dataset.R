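# ConnectivityDataset construction, accessors, and CSV round-trip.

#' Construct a ConnectivityDataset
#'
#' @param z pairs-by-subjects matrix of Fisher-z connectivity values, rows
#'   in canonical pair order.
#' @param manifest data.frame with \code{subject_id}, \code{group} (0/1),
#'   \code{site} and any additional subject covariates.
#' @param roiLabels character vector of ROI labels; its length R must
#'   satisfy \code{nrow(z) == R(R-1)/2}.
#' @param options list of processing options stored in \code{metadata()}.
#' @return A \linkS4class{ConnectivityDataset}.
#' @export
connectivityDataset <- function(z, manifest, roiLabels, options = list()) {
  R <- length(roiLabels)
  if (nrow(z) != R * (R - 1) / 2)
    stop("nrow(z) must equal length(roiLabels) choose 2")
  pt <- pairIndexTable(R, roiLabels)
  rd <- DataFrame(roi1 = pt$roi1, roi2 = pt$roi2,
                  label1 = pt$label1, label2 = pt$label2)
  rownames(z) <- pt$name
  cd <- DataFrame(manifest, row.names = manifest$subject_id)
  cd$group <- as.integer(cd$group)
  se <- SummarizedExperiment(assays = list(z = z), rowData = rd,
                             colData = cd)
  metadata(se)$options <- options
  new("ConnectivityDataset", se)
}

#' @describeIn connectivityDataset subjects-by-pairs feature matrix (the
#'   modeling orientation).
#' @param x a \linkS4class{ConnectivityDataset}.
#' @export
featureMatrix <- function(x) t(assay(x, "z"))

#' @describeIn connectivityDataset 0/1 diagnosis labels (1 = AD).
#' @export
groupLabels <- function(x) as.integer(colData(x)$group)

#' @describeIn connectivityDataset per-subject site labels.
#' @export
siteLabels <- function(x) as.character(colData(x)$site)

#' @describeIn connectivityDataset canonical pair index as a data.frame.
#' @export
pairInfo <- function(x) as.data.frame(rowData(x))

#' Write a feature dataset as CSV + JSON sidecar
#'
#' One row per subject: \code{subject_id}, \code{group}, \code{site}, then
#' one column per pair named \code{"ROIi__ROIj"}. Processing options go to
#' \code{<path>.json}.
#'
#' @param x a \linkS4class{ConnectivityDataset}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureDataset <- function(x, path) {
  df <- data.frame(subject_id = colnames(x),
                   group = groupLabels(x),
                   site = siteLabels(x),
                   featureMatrix(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  side <- list(options = metadata(x)$options,
               n_roi = max(pairInfo(x)$roi2), n_pairs = nrow(x))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature dataset written by \code{\link{writeFeatureDataset}}
#'
#' @param path CSV path.
#' @return A \linkS4class{ConnectivityDataset}.
#' @export
readFeatureDataset <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- names(df) %in% c("subject_id", "group", "site")
  z <- t(as.matrix(df[, !meta, drop = FALSE]))
  pairNames <- rownames(z)
  labels <- unique(unlist(strsplit(pairNames, "__", fixed = TRUE)))
  manifest <- df[, meta, drop = FALSE]
  opts <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    opts <- jsonlite::read_json(sidecar, simplifyVector = TRUE)$options
  connectivityDataset(z, manifest, labels, options = opts)
}
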