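#' @include AllClasses.R
NULL

#' Number of samples in an object
#' @param x an object with per-sample records.
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Number of sensors
#' @param x an object carrying a sensor dimension.
#' @return integer sensor count.
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' Number of time points per response curve
#' @param x an [ENoseDataset-class].
#' @return integer time-point count.
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Sampling interval in seconds
#' @param x an [ENoseDataset-class].
#' @return numeric scalar dt.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' Per-sample class labels
#' @param x a dataset, feature matrix or score matrix.
#' @return factor of labels; level order is class order.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Per-sample identifiers
#' @param x a dataset, feature matrix or score matrix.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Ordered distinct class labels
#' @param x a dataset, feature matrix, score matrix or centroid set.
#' @return character vector; position g is the label of class index g.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' Extract one sample's response curve
#' @param x an [ENoseDataset-class].
#' @param i sample index or sample id.
#' @return numeric sensors x time matrix of G/G0 ratios.
#' @export
setGeneric("responseCurve", function(x, i) standardGeneric("responseCurve"))

#' Numeric values of a derived matrix object
#' @param x a [FeatureMatrix-class] or [ScoreMatrix-class].
#' @return the underlying numeric matrix (samples in rows).
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Score values of a ScoreMatrix
#' @param x a [ScoreMatrix-class].
#' @return numeric samples x components matrix.
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
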