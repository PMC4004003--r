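#' @include AllClasses.R
NULL

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "enoseWilks")
  if (p == "") stop("bundled data file not found: ", file)
  p
}

#' Published PCA eigenvalues of the rough-rice experiment
#'
#' The ten covariance eigenvalues reported for a 120-sample, 10-sensor
#' rough-rice e-nose experiment (six varieties, D_ave features). Bundled as
#' reference input for the explained-variance arithmetic; the underlying raw
#' sensor data were never deposited.
#'
#' @return named numeric vector of 10 eigenvalues, descending.
#' @examples
#' round(explainedVariancePct(riceEigenvalues(), c(1, 2)), 2)
#' @export
riceEigenvalues <- function() {
  df <- utils::read.csv(.extdata("rice_eigenvalues.csv"))
  stats::setNames(df$eigenvalue, paste0("PC", df$pc))
}

#' Published dispersion-ratio table of the rough-rice experiment
#'
#' The 45 pairwise dispersion ratios (absolute-value Wilks Lambda over all
#' unordered principal-component pairs) reported for the rough-rice
#' experiment, as a precomputed table suitable for [selectBestPair()].
#'
#' @return data.frame with columns `i`, `j`, `lambda` (45 rows).
#' @examples
#' selectBestPair(riceDispersionTable())
#' @export
riceDispersionTable <- function() {
  utils::read.csv(.extdata("rice_dispersion_ratios.csv"))
}

#' Published PNN confusion matrices of the rough-rice experiment
#'
#' The 6 x 6 test-set confusion matrices (30 test samples, spread 4e-5)
#' reported for PNN classification on the baseline pair (PC1, PC2) and on the
#' dispersion-ratio-selected pair (PC1, PC5).
#'
#' @param pair `"pc1_pc2"` (baseline) or `"pc1_pc5"` (selected pair).
#' @return integer matrix, rows = true class, columns = predicted class.
#' @examples
#' confusionAccuracy(riceConfusion("pc1_pc5"))
#' @export
riceConfusion <- function(pair = c("pc1_pc2", "pc1_pc5")) {
  pair <- match.arg(pair)
  df <- utils::read.csv(.extdata(paste0("rice_confusion_", pair, ".csv")),
                        check.names = FALSE)
  m <- as.matrix(df[, -1L])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = df$true, predicted = colnames(m))
  m
}
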