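#' @include AllClasses.R
NULL

#' Mean differential coefficient of a response curve
#'
#' The D_ave feature: the average first difference of a sensor's response
#' series per unit time,
#' `(1/(n-1)) * sum_{z=1}^{n-1} (x[z+1] - x[z]) / dt`.
#' The sum telescopes, so this equals `(x[n] - x[1]) / ((n-1) * dt)`; the
#' closed form is the production path (`method = "closed"`) and the literal
#' summation (`method = "sum"`) is retained for cross-checking.
#'
#' @param x numeric response series (G/G0 ratios), length >= 2.
#' @param dt sampling interval in seconds (> 0).
#' @param method `"closed"` (default) or `"sum"`.
#' @return D_ave in ratio units per second.
#' @examples
#' dave(seq_len(80))            # unit slope -> 1
#' dave(rep(2, 80))             # flat curve -> 0
#' @export
dave <- function(x, dt = 1, method = c("closed", "sum")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2L) stop("insufficient data: series length must be >= 2")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (method == "closed") {
    (x[n] - x[1L]) / ((n - 1) * dt)
  } else {
    sum(diff(x) / dt) / (n - 1)
  }
}

#' Extract D_ave features from a dataset
#'
#' Applies [dave()] to every (sample, sensor) response series, producing the
#' samples x sensors feature matrix that feeds the PCA stage.
#'
#' @param ds an [ENoseDataset-class] whose curves have >= 2 time points.
#' @return a [FeatureMatrix-class], entry (k, s) = D_ave of sensor s of
#'   sample k; label and sample order preserved.
#' @export
extractFeatures <- function(ds) {
  stopifnot(is(ds, "ENoseDataset"))
  nT <- nTimePoints(ds)
  if (nT < 2L) stop("insufficient data: curves need >= 2 time points")
  # telescoped closed form applied to the whole array at once
  nS <- nSensors(ds)
  last <- matrix(ds@responses[, nT, ], nrow = nS)
  first <- matrix(ds@responses[, 1L, ], nrow = nS)
  vals <- t((last - first) / ((nT - 1) * ds@dt))
  FeatureMatrix(vals, ds@sampleIds, ds@classLabels)
}
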