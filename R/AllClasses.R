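#' @import methods
NULL

#' ENoseDataset: a set of electronic-nose response curves
#'
#' Container for a collection of e-nose sample measurements. Each sample is a
#' sensors x time matrix of conductance ratios R = G/G0, where G is the sensor
#' resistance during sample exposure and G0 its value in cleaned reference
#' ("zero") gas. All samples in a dataset share the sensor count, the time
#' grid, and the sampling interval.
#'
#' Class order (the levels of `classLabels`) is the order of first appearance
#' and determines the class index used in every downstream report.
#'
#' @slot responses numeric array, `n_sensors x n_time x n_samples`, all
#'   entries strictly positive (they are resistance ratios).
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot classLabels factor of class labels, one per sample; level order is
#'   first-appearance order.
#' @slot dt sampling interval in seconds (scalar, > 0).
#'
#' @seealso [ENoseDataset()], [readResponseCSV()], [simulateENose()]
#' @export
setClass("ENoseDataset",
  representation(
    responses = "array",
    sampleIds = "character",
    classLabels = "factor",
    dt = "numeric"
  )
)

setValidity("ENoseDataset", function(object) {
  d <- dim(object@responses)
  if (length(d) != 3L)
    return("'responses' must be a 3-d array (sensors x time x samples)")
  if (d[2L] < 2L)
    return("at least 2 time points are required")
  if (length(object@sampleIds) != d[3L])
    return("length(sampleIds) must equal the number of samples")
  if (length(object@classLabels) != d[3L])
    return("length(classLabels) must equal the number of samples")
  if (anyDuplicated(object@sampleIds))
    return("sample ids must be unique")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("'dt' must be a single positive number")
  if (!all(is.finite(object@responses)))
    return("response values must be finite")
  if (any(object@responses <= 0))
    return("response ratios must be strictly positive")
  TRUE
})

#' Construct an ENoseDataset
#'
#' @param responses numeric array `n_sensors x n_time x n_samples` of strictly
#'   positive G/G0 ratios.
#' @param sampleIds character vector of unique sample identifiers.
#' @param classLabels character or factor of per-sample class labels. When a
#'   character vector is given, class order is the order of first appearance.
#' @param dt sampling interval in seconds (default 1).
#' @return an [ENoseDataset-class] object.
#' @examples
#' arr <- array(runif(2 * 5 * 3, 1, 2), dim = c(2, 5, 3))
#' ds <- ENoseDataset(arr, paste0("s", 1:3), c("A", "A", "B"))
#' nSamples(ds)
#' @export
ENoseDataset <- function(responses, sampleIds, classLabels, dt = 1) {
  if (!is.factor(classLabels))
    classLabels <- factor(classLabels, levels = unique(as.character(classLabels)))
  new("ENoseDataset",
    responses = responses,
    sampleIds = as.character(sampleIds),
    classLabels = classLabels,
    dt = as.numeric(dt)
  )
}

#' FeatureMatrix: per-sample, per-sensor scalar features
#'
#' Samples x sensors matrix of mean-differential-coefficient (D_ave) features,
#' in ratio units per second, with the per-sample class labels.
#'
#' @slot values numeric matrix, `n_samples x n_sensors`, finite entries.
#' @slot sampleIds character vector, one id per row.
#' @slot classLabels factor, one label per row.
#' @seealso [extractFeatures()]
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    sampleIds = "character",
    classLabels = "factor"
  )
)

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@classLabels))
    return("one class label per feature row required")
  if (nrow(object@values) != length(object@sampleIds))
    return("one sample id per feature row required")
  if (!all(is.finite(object@values)))
    return("feature values must be finite (no NaN/Inf)")
  TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric samples x sensors matrix.
#' @param sampleIds character vector of row identifiers.
#' @param classLabels character or factor of per-row class labels.
#' @return a [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, sampleIds, classLabels) {
  if (!is.factor(classLabels))
    classLabels <- factor(classLabels, levels = unique(as.character(classLabels)))
  values <- as.matrix(values)
  rownames(values) <- as.character(sampleIds)
  new("FeatureMatrix", values = values,
      sampleIds = as.character(sampleIds), classLabels = classLabels)
}

#' PCAModel: covariance-based principal component model
#'
#' Eigendecomposition of the sample covariance matrix (divisor n - 1) of
#' mean-centered features. Loadings columns are orthonormal eigenvectors in
#' descending eigenvalue order, with a deterministic sign convention: each
#' eigenvector is flipped so that its largest-magnitude entry is positive
#' (ties broken by lowest index).
#'
#' @slot center per-variable mean of the fitting data.
#' @slot loadings orthonormal matrix, variables x components.
#' @slot eigenvalues non-negative, descending.
#' @seealso [fitPCA()], [pcaTransform()], [explainedVariancePct()]
#' @export
setClass("PCAModel",
  representation(
    center = "numeric",
    loadings = "matrix",
    eigenvalues = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  p <- length(object@center)
  L <- object@loadings
  if (nrow(L) != p)
    return("loadings row count must equal length(center)")
  if (length(object@eigenvalues) != ncol(L))
    return("one eigenvalue per loading column required")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted descending")
  if (any(object@eigenvalues < 0))
    return("eigenvalues must be non-negative")
  G <- crossprod(L)
  if (max(abs(G - diag(ncol(L)))) > 1e-10)
    return("loadings columns must be orthonormal (tolerance 1e-10)")
  TRUE
})

#' ScoreMatrix: samples projected onto principal components
#'
#' @slot scores numeric matrix, samples x components, in feature units.
#' @slot sampleIds character vector, one per row.
#' @slot classLabels factor, one per row.
#' @slot componentIds integer vector of 1-based principal-component indices
#'   (column `k` of `scores` is component `componentIds[k]`).
#' @seealso [pcaTransform()]
#' @export
setClass("ScoreMatrix",
  representation(
    scores = "matrix",
    sampleIds = "character",
    classLabels = "factor",
    componentIds = "integer"
  )
)

setValidity("ScoreMatrix", function(object) {
  if (nrow(object@scores) != length(object@classLabels))
    return("one class label per score row required")
  if (nrow(object@scores) != length(object@sampleIds))
    return("one sample id per score row required")
  if (ncol(object@scores) != length(object@componentIds))
    return("one component id per score column required")
  if (any(object@componentIds < 1L))
    return("component ids are 1-based positive integers")
  TRUE
})

#' ScatterPair: within-class and total scatter matrices
#'
#' The pair (D, A) of scatter matrices over a set of selected principal
#' components: D sums deviation cross-products around class means, A around
#' the grand mean. In the `"regular"` variant the cross-products are summed as
#' they are; in the `"improved"` variant each cross-product is replaced by its
#' absolute value before summation, so that terms of opposite sign cannot
#' cancel. Diagonal entries (squares) are identical between variants.
#'
#' @slot D within-class scatter matrix (m x m).
#' @slot A total scatter matrix (m x m).
#' @slot variant `"regular"` or `"improved"`.
#' @slot componentIds the m selected 1-based component indices.
#' @seealso [scatterMatrices()], [wilksLambda()]
#' @export
setClass("ScatterPair",
  representation(
    D = "matrix",
    A = "matrix",
    variant = "character",
    componentIds = "integer"
  )
)

setValidity("ScatterPair", function(object) {
  if (!identical(dim(object@D), dim(object@A)))
    return("D and A must have identical dimensions")
  if (!object@variant %in% c("regular", "improved"))
    return("variant must be 'regular' or 'improved'")
  scale <- max(1, max(abs(object@A)))
  if (max(abs(object@D - t(object@D))) > 1e-12 * scale)
    return("D must be symmetric")
  if (max(abs(object@A - t(object@A))) > 1e-12 * scale)
    return("A must be symmetric")
  if (any(diag(object@D) > diag(object@A) + 1e-9 * scale))
    return("diagonal of D cannot exceed diagonal of A")
  TRUE
})

#' WilksReport: dispersion ratios over all component pairs
#'
#' Result of an exhaustive search over unordered component pairs (i, j),
#' i < j, for the pair minimising the Wilks Lambda dispersion ratio
#' det(D)/det(A).
#'
#' @slot table data.frame with columns `i`, `j`, `lambda`, one row per pair,
#'   ordered by (i, j).
#' @slot variant `"regular"` or `"improved"`.
#' @slot bestPair integer pair (i, j) attaining the minimum (lexicographic
#'   lowest on ties).
#' @slot bestValue the minimum dispersion ratio, full precision.
#' @seealso [pairSearch()], [selectBestPair()]
#' @export
setClass("WilksReport",
  representation(
    table = "data.frame",
    variant = "character",
    bestPair = "integer",
    bestValue = "numeric"
  )
)

setValidity("WilksReport", function(object) {
  tb <- object@table
  if (!all(c("i", "j", "lambda") %in% names(tb)))
    return("table must have columns i, j, lambda")
  if (any(tb$lambda < 0))
    return("dispersion ratios must be non-negative")
  if (!length(object@bestPair) %in% c(2L, 3L))
    return("bestPair must hold 2 (pair search) or 3 (triple search) indices")
  if (abs(object@bestValue - min(tb$lambda)) > 0)
    return("bestValue must equal the table minimum")
  TRUE
})

#' CentroidSet: class centroids and pooled within-class covariance
#'
#' Per-class mean points in a 2-component score space, together with the
#' pooled within-class covariance (divisor N - c) used for Mahalanobis
#' distances between centroids.
#'
#' @slot centroids numeric matrix, classes x 2, rownames are class labels.
#' @slot pooledCov 2 x 2 pooled within-class covariance, symmetric PSD.
#' @slot classes character vector of class labels in dataset order.
#' @seealso [classCentroids()], [pairwiseMahalanobis()]
#' @export
setClass("CentroidSet",
  representation(
    centroids = "matrix",
    pooledCov = "matrix",
    classes = "character"
  )
)

setValidity("CentroidSet", function(object) {
  if (ncol(object@centroids) != 2L)
    return("centroids live in a 2-component space")
  if (nrow(object@centroids) != length(object@classes))
    return("one centroid per class required")
  S <- object@pooledCov
  if (!identical(dim(S), c(2L, 2L)))
    return("pooledCov must be 2 x 2")
  scale <- max(1e-300, max(abs(S)))
  if (abs(S[1, 2] - S[2, 1]) > 1e-12 * scale)
    return("pooledCov must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * scale)
    return("pooledCov must be positive semi-definite")
  TRUE
})

#' PNNModel: probabilistic neural network classifier
#'
#' A Parzen-kernel classifier with one pattern neuron per training sample.
#' With the `"dot_product"` kernel, patterns and queries are normalised to
#' unit length and a pattern's activation for query q is
#' `g(z) = exp((z - 1) / spread^2)` with `z = <q, w>`; with the `"euclidean"`
#' kernel it is `exp(-||q - w||^2 / (2 spread^2))`. Class scores are the sums
#' of the class's pattern activations; the predicted class is the arg-max.
#'
#' @slot patterns stored training vectors (rows), unit-normalised for the
#'   dot-product kernel.
#' @slot patternClass factor, class of each pattern neuron.
#' @slot spread kernel bandwidth sigma (> 0).
#' @slot kernel `"dot_product"` or `"euclidean"`.
#' @slot normalize whether inputs were unit-normalised at training time.
#' @seealso [trainPNN()], [evaluatePNN()], [spreadGridSearch()]
#' @export
setClass("PNNModel",
  representation(
    patterns = "matrix",
    patternClass = "factor",
    spread = "numeric",
    kernel = "character",
    normalize = "logical"
  )
)

setValidity("PNNModel", function(object) {
  if (nrow(object@patterns) != length(object@patternClass))
    return("one pattern neuron per training sample required")
  if (length(object@spread) != 1L || object@spread <= 0)
    return("spread must be a single positive number")
  if (!object@kernel %in% c("dot_product", "euclidean"))
    return("kernel must be 'dot_product' or 'euclidean'")
  if (object@kernel == "dot_product" && object@normalize) {
    nrm <- sqrt(rowSums(object@patterns^2))
    if (any(abs(nrm - 1) > 1e-10))
      return("dot_product patterns must be unit-norm (tolerance 1e-10)")
  }
  TRUE
})

#' SynthConfig: synthetic e-nose dataset configuration
#'
#' Parameters of the first-order-kinetics response generator: sample k of
#' class g on sensor s draws an asymptote
#' `theta* = theta[g, s] + N(0, withinSd[s])` and produces the curve
#' `R(t) = 1 + (theta* - 1) (1 - exp(-t / tau)) + N(0, noiseSd)` at
#' t = dt, 2 dt, ..., nTime dt, clipped below at 1e-6.
#'
#' @slot nClasses number of classes (default 6).
#' @slot nPerClass samples per class (default 20).
#' @slot nSensors sensors in the array (default 10).
#' @slot nTime time points per curve (default 80).
#' @slot dt sampling interval, seconds (default 1).
#' @slot tau first-order rise time constant, seconds.
#' @slot theta nClasses x nSensors matrix of response asymptotes (> 0).
#' @slot withinSd per-sensor within-class standard deviation of the asymptote.
#' @slot noiseSd additive per-time-point measurement noise sd.
#' @slot seed integer RNG seed (NA for the current RNG state).
#' @seealso [synthConfig()], [simulateENose()], [enoseScenario()]
#' @export
setClass("SynthConfig",
  representation(
    nClasses = "integer",
    nPerClass = "integer",
    nSensors = "integer",
    nTime = "integer",
    dt = "numeric",
    tau = "numeric",
    theta = "matrix",
    withinSd = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  cnt <- c(object@nClasses, object@nPerClass, object@nSensors, object@nTime)
  if (any(cnt < 1L))
    return("all counts must be >= 1")
  if (object@nTime < 2L)
    return("at least 2 time points are required")
  if (object@dt <= 0 || object@tau <= 0)
    return("dt and tau must be positive")
  if (!identical(dim(object@theta),
                 c(object@nClasses, object@nSensors)))
    return("theta must be nClasses x nSensors")
  if (any(object@theta <= 0))
    return("theta asymptotes must be positive")
  if (length(object@withinSd) != object@nSensors)
    return("withinSd must have one entry per sensor")
  if (any(object@withinSd < 0) || any(object@noiseSd < 0))
    return("withinSd and noiseSd must be non-negative")
  TRUE
})
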