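#' @include AllClasses.R
NULL

# Deterministic eigenvector sign convention: flip each column so its
# largest-magnitude entry is positive; ties broken by lowest index
# (which.max returns the first maximum).
.fixSigns <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Fit a covariance-based PCA model
#'
#' Eigendecomposition of the sample covariance matrix (divisor n - 1) of the
#' mean-centered, unstandardised feature matrix. No correlation scaling is
#' applied: D_ave features share units, and the raw-scale eigenvalue spectrum
#' is what the dispersion-ratio pair search operates on. Eigenvalues below 0
#' by numerical error (>= -1e-12 relative) are clipped to 0.
#'
#' @param fm a [FeatureMatrix-class] or plain numeric matrix with >= 2 rows.
#' @return a [PCAModel-class].
#' @seealso [pcaTransform()], [explainedVariancePct()]
#' @export
fitPCA <- function(fm) {
  X <- if (is(fm, "FeatureMatrix")) fm@values else as.matrix(fm)
  if (nrow(X) < 2L) stop("insufficient data: PCA needs >= 2 samples")
  ctr <- colMeans(X)
  S <- stats::cov(X)
  eig <- eigen(S, symmetric = TRUE)
  ev <- eig$values
  scale <- max(abs(ev), 1e-300)
  if (any(ev < -1e-12 * scale))
    stop("covariance matrix is not PSD beyond numerical tolerance")
  ev <- pmax(ev, 0)
  new("PCAModel", center = as.numeric(ctr),
      loadings = .fixSigns(eig$vectors), eigenvalues = ev)
}

#' Project features onto principal components
#'
#' Computes `(features - center) %*% loadings`, retaining all components.
#'
#' @param model a [PCAModel-class].
#' @param fm a [FeatureMatrix-class] (or numeric matrix, in which case labels
#'   are empty) whose column count matches the model dimension.
#' @return a [ScoreMatrix-class] with componentIds `1..n`.
#' @export
pcaTransform <- function(model, fm) {
  stopifnot(is(model, "PCAModel"))
  if (is(fm, "FeatureMatrix")) {
    X <- fm@values; ids <- fm@sampleIds; lab <- fm@classLabels
  } else {
    X <- as.matrix(fm)
    ids <- if (!is.null(rownames(X))) rownames(X) else
      paste0("row", seq_len(nrow(X)))
    lab <- factor(rep("unlabelled", nrow(X)))
  }
  if (ncol(X) != length(model@center))
    stop("shape error: feature dimension does not match the PCA model")
  sc <- sweep(X, 2L, model@center) %*% model@loadings
  new("ScoreMatrix", scores = unname(sc), sampleIds = ids, classLabels = lab,
      componentIds = seq_len(ncol(sc)))
}

#' Restrict a ScoreMatrix to selected components
#'
#' @param sm a [ScoreMatrix-class].
#' @param components 1-based principal-component indices to keep.
#' @return a [ScoreMatrix-class] with just those columns, in the given order.
#' @export
selectComponents <- function(sm, components) {
  stopifnot(is(sm, "ScoreMatrix"))
  idx <- match(as.integer(components), sm@componentIds)
  if (anyNA(idx)) stop("unknown component id(s): ",
                       paste(components[is.na(idx)], collapse = ", "))
  new("ScoreMatrix", scores = sm@scores[, idx, drop = FALSE],
      sampleIds = sm@sampleIds, classLabels = sm@classLabels,
      componentIds = sm@componentIds[idx])
}

#' Percentage of variance explained by a component subset
#'
#' `100 * sum(lambda[components]) / sum(lambda)`. Full precision is returned;
#' user-facing reports round to 2 decimals.
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param components 1-based indices of the components of interest.
#' @return percentage in `[0, 100]`, full precision.
#' @examples
#' explainedVariancePct(c(4, 2, 1, 1), c(1, 2))  # 75
#' @export
explainedVariancePct <- function(eigenvalues, components) {
  if (length(components) == 0L)
    stop("value error: empty component set")
  components <- as.integer(components)
  if (any(components < 1L) || any(components > length(eigenvalues)))
    stop("value error: component index out of range")
  100 * sum(eigenvalues[components]) / sum(eigenvalues)
}
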