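#' @include AllGenerics.R
NULL

#' @describeIn ENoseDataset-class number of samples
#' @param x object.
#' @aliases nSamples,ENoseDataset-method
#' @export
setMethod("nSamples", "ENoseDataset", function(x) dim(x@responses)[3L])

#' @describeIn ENoseDataset-class number of sensors
#' @export
setMethod("nSensors", "ENoseDataset", function(x) dim(x@responses)[1L])

#' @describeIn ENoseDataset-class number of time points
#' @export
setMethod("nTimePoints", "ENoseDataset", function(x) dim(x@responses)[2L])

#' @describeIn ENoseDataset-class sampling interval (s)
#' @export
setMethod("samplingInterval", "ENoseDataset", function(x) x@dt)

#' @describeIn ENoseDataset-class per-sample class labels
#' @export
setMethod("classLabels", "ENoseDataset", function(x) x@classLabels)

#' @describeIn ENoseDataset-class per-sample ids
#' @export
setMethod("sampleIds", "ENoseDataset", function(x) x@sampleIds)

#' @describeIn ENoseDataset-class ordered distinct classes
#' @export
setMethod("classNames", "ENoseDataset", function(x) levels(x@classLabels))

#' @describeIn ENoseDataset-class one sample's sensors x time matrix
#' @param i sample index or id
#' @export
setMethod("responseCurve", "ENoseDataset", function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@sampleIds)
    if (is.na(i)) stop("unknown sample id")
  }
  x@responses[, , i, drop = FALSE][, , 1L]
})

setMethod("show", "ENoseDataset", function(object) {
  cat(sprintf(
    "ENoseDataset: %d samples, %d classes, %d sensors x %d time points (dt = %g s)\n",
    nSamples(object), nlevels(object@classLabels),
    nSensors(object), nTimePoints(object), object@dt))
  cat("classes:", paste(levels(object@classLabels), collapse = ", "), "\n")
})

#' @describeIn FeatureMatrix-class number of samples (rows)
#' @param x object.
#' @export
setMethod("nSamples", "FeatureMatrix", function(x) nrow(x@values))

#' @describeIn FeatureMatrix-class number of sensors (columns)
#' @export
setMethod("nSensors", "FeatureMatrix", function(x) ncol(x@values))

#' @describeIn FeatureMatrix-class per-row class labels
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) x@classLabels)

#' @describeIn FeatureMatrix-class per-row sample ids
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) x@sampleIds)

#' @describeIn FeatureMatrix-class ordered distinct classes
#' @export
setMethod("classNames", "FeatureMatrix", function(x) levels(x@classLabels))

#' @describeIn FeatureMatrix-class the samples x sensors value matrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d sensors (D_ave, ratio/s)\n",
              nrow(object@values), ncol(object@values)))
})

#' @describeIn ScoreMatrix-class number of samples (rows)
#' @param x object.
#' @export
setMethod("nSamples", "ScoreMatrix", function(x) nrow(x@scores))

#' @describeIn ScoreMatrix-class per-row class labels
#' @export
setMethod("classLabels", "ScoreMatrix", function(x) x@classLabels)

#' @describeIn ScoreMatrix-class per-row sample ids
#' @export
setMethod("sampleIds", "ScoreMatrix", function(x) x@sampleIds)

#' @describeIn ScoreMatrix-class ordered distinct classes
#' @export
setMethod("classNames", "ScoreMatrix", function(x) levels(x@classLabels))

#' @describeIn ScoreMatrix-class the samples x components score matrix
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d samples x %d components (PC%s)\n",
              nrow(object@scores), ncol(object@scores),
              paste(object@componentIds, collapse = ", PC")))
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@eigenvalues
  tot <- sum(ev)
  cat(sprintf("PCAModel: %d variables, %d components\n",
              length(object@center), length(ev)))
  cat("eigenvalues:", paste(signif(ev, 5), collapse = ", "), "\n")
  if (tot > 0)
    cat(sprintf("PC1+PC2 explained variance: %.2f%%\n",
                100 * sum(ev[seq_len(min(2, length(ev)))]) / tot))
})

setMethod("show", "WilksReport", function(object) {
  cat(sprintf("WilksReport (%s variant): %d component pairs\n",
              object@variant, nrow(object@table)))
  cat(sprintf("best pair: (PC%d, PC%d), dispersion ratio = %.4f\n",
              object@bestPair[1L], object@bestPair[2L], object@bestValue))
})

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d class centroids in a 2-PC space\n",
              nrow(object@centroids)))
  print(round(object@centroids, 4))
})

setMethod("show", "PNNModel", function(object) {
  cat(sprintf(
    "PNNModel: %d pattern neurons, %d classes, kernel = %s, spread = %g\n",
    nrow(object@patterns), nlevels(object@patternClass),
    object@kernel, object@spread))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d classes x %d samples, %d sensors x %d time points (dt = %g s, tau = %g s)\n",
    object@nClasses, object@nPerClass, object@nSensors, object@nTime,
    object@dt, object@tau))
})

#' Extract the Wilks pair table
#'
#' @param report a [WilksReport-class].
#' @param digits if non-NULL, round `lambda` for display (selection always
#'   uses full precision).
#' @return data.frame with columns `i`, `j`, `lambda`.
#' @export
wilksTable <- function(report, digits = NULL) {
  stopifnot(is(report, "WilksReport"))
  tb <- report@table
  if (!is.null(digits)) tb$lambda <- round(tb$lambda, digits)
  tb
}

#' Best component pair of a Wilks report
#'
#' @param report a [WilksReport-class].
#' @return list with `pair` (integer 2-vector) and `value` (the minimum
#'   dispersion ratio at full precision).
#' @export
bestPair <- function(report) {
  stopifnot(is(report, "WilksReport"))
  list(pair = report@bestPair, value = report@bestValue)
}
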