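#' @include AllClasses.R
NULL

.unitRows <- function(X, what) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("value error: zero-norm ", what, " under the dot_product kernel")
  X / nrm
}

#' Train a probabilistic neural network
#'
#' A PNN stores one pattern neuron per training sample — there is no
#' iterative fitting. With the default `"dot_product"` kernel the stored
#' patterns (and later the queries) are normalised to unit length, so the
#' activation `exp((z - 1)/spread^2)` with `z` the dot product equals the
#' Gaussian kernel `exp(-||q - w||^2 / (2 spread^2))` on the unit sphere.
#' The `"euclidean"` kernel applies the Gaussian to the raw vectors instead
#' (the behaviour of classical PNN implementations on unnormalised data).
#'
#' @param scores a [ScoreMatrix-class] or numeric samples x d matrix of
#'   training vectors.
#' @param labels class labels (taken from a [ScoreMatrix-class] input).
#' @param spread kernel bandwidth sigma (> 0).
#' @param kernel `"dot_product"` (default) or `"euclidean"`.
#' @param normalize unit-normalise inputs (required and TRUE by default for
#'   `"dot_product"`; optional for `"euclidean"`).
#' @return a [PNNModel-class].
#' @export
trainPNN <- function(scores, labels = NULL, spread,
                     kernel = c("dot_product", "euclidean"),
                     normalize = NULL) {
  kernel <- match.arg(kernel)
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0)
    stop("value error: spread must be a single positive number")
  inp <- .scoreInput(scores, labels)
  X <- inp$X
  labels <- if (is.factor(inp$labels)) inp$labels else
    factor(inp$labels, levels = unique(as.character(inp$labels)))
  if (any(tabulate(labels, nlevels(labels)) == 0L))
    stop("every class needs at least one training sample")
  if (is.null(normalize)) normalize <- kernel == "dot_product"
  if (kernel == "dot_product" && !normalize)
    stop("the dot_product kernel requires unit-normalised patterns")
  if (normalize) X <- .unitRows(X, "training vector")
  new("PNNModel", patterns = unname(X), patternClass = labels,
      spread = spread, kernel = kernel, normalize = normalize)
}

# Per-pattern log-activations for a single query vector.
.logActivations <- function(model, q) {
  if (model@kernel == "dot_product") {
    if (model@normalize) {
      nrm <- sqrt(sum(q^2))
      if (nrm == 0)
        stop("value error: zero-norm query under the dot_product kernel")
      q <- q / nrm
    }
    z <- as.numeric(model@patterns %*% q)
    (z - 1) / model@spread^2
  } else {
    d2 <- rowSums(sweep(model@patterns, 2L, q)^2)
    -d2 / (2 * model@spread^2)
  }
}

#' Classify query vectors with a PNN
#'
#' For each query, pattern activations are summed per class and the class
#' with the largest summed activation wins; exact ties resolve to the lowest
#' class index and are flagged. To stay numerically meaningful at very small
#' spreads (where `exp((z - 1)/spread^2)` underflows for every pattern), the
#' activations are rescaled so the largest pattern activation is exactly 1;
#' this multiplies every class score by the same positive constant and leaves
#' the arg-max — and the nearest-neighbour small-spread limit — unchanged.
#'
#' @param object a [PNNModel-class].
#' @param newdata a query vector, a numeric queries x d matrix, or a
#'   [ScoreMatrix-class].
#' @param ... unused.
#' @return list with `class` (factor of predictions), `activations`
#'   (queries x classes matrix of summed, max-rescaled activations) and
#'   `tie` (logical per query).
#' @export
setMethod("predict", "PNNModel", function(object, newdata, ...) {
  Q <- if (is(newdata, "ScoreMatrix")) newdata@scores else
    if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(Q) != ncol(object@patterns))
    stop("shape error: query dimension does not match the stored patterns")
  cls <- levels(object@patternClass)
  g <- length(cls)
  acts <- matrix(0, nrow(Q), g, dimnames = list(NULL, cls))
  pred <- integer(nrow(Q))
  tie <- logical(nrow(Q))
  for (r in seq_len(nrow(Q))) {
    la <- .logActivations(object, Q[r, ])
    a <- exp(la - max(la))                  # rescale: max activation = 1
    sums <- as.numeric(rowsum(a, object@patternClass))
    best <- max(sums)
    winners <- which(sums == best)
    pred[r] <- winners[1L]
    tie[r] <- length(winners) > 1L
    acts[r, ] <- sums
  }
  list(class = factor(cls[pred], levels = cls), activations = acts, tie = tie)
})

#' Accuracy of a confusion matrix
#'
#' `100 * trace / total`: the percentage of test samples on the diagonal.
#'
#' @param counts square matrix of counts, rows = true class, columns =
#'   predicted class.
#' @param digits decimals for rounding (default 2, the reporting convention);
#'   use `NULL` for full precision.
#' @return accuracy percentage.
#' @examples
#' confusionAccuracy(diag(5))  # 100
#' @export
confusionAccuracy <- function(counts, digits = 2) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  acc <- 100 * sum(diag(counts)) / sum(counts)
  if (is.null(digits)) acc else round(acc, digits)
}

#' Evaluate a PNN on a labelled test set
#'
#' @param model a [PNNModel-class].
#' @param scores test queries ([ScoreMatrix-class] or matrix).
#' @param labels true labels; every label must be a class seen in training.
#' @return list with `confusion` (classes x classes integer matrix, rows =
#'   true), `accuracy` (percentage, full precision) and `accuracyPct`
#'   (rounded to 2 decimals).
#' @export
evaluatePNN <- function(model, scores, labels = NULL) {
  stopifnot(is(model, "PNNModel"))
  inp <- .scoreInput(scores, labels)
  if (nrow(inp$X) == 0L) stop("empty test set")
  cls <- levels(model@patternClass)
  labels <- as.character(inp$labels)
  if (!all(labels %in% cls))
    stop("value error: test label(s) unseen in training: ",
         paste(setdiff(labels, cls), collapse = ", "))
  pr <- predict(model, inp$X)
  cm <- table(factor(labels, levels = cls), pr$class)
  cm <- matrix(as.integer(cm), nrow = length(cls),
               dimnames = list(true = cls, predicted = cls))
  list(confusion = cm,
       accuracy = confusionAccuracy(cm, digits = NULL),
       accuracyPct = confusionAccuracy(cm, digits = 2))
}

#' The canonical ten-point spread grid
#'
#' `1e-5, 2e-5, ..., 1e-4`: the bandwidth range over which the PNN is tuned
#' for PC-score inputs of magnitude ~1e-2.
#'
#' @return numeric vector of 10 spread values.
#' @export
defaultSpreadGrid <- function() seq(1e-5, 1e-4, by = 1e-5)

#' Grid search over the PNN spread
#'
#' Trains and evaluates a PNN at every spread in the grid and selects the
#' model whose training-set and test-set accuracies are jointly highest
#' (lexicographic maximum on (train accuracy, test accuracy)); among equally
#' good spreads the smallest is chosen. Comparisons use full-precision
#' accuracies.
#'
#' @param trainScores,trainLabels training data.
#' @param testScores,testLabels test data.
#' @param grid spread values to try (default [defaultSpreadGrid()]).
#' @param kernel forwarded to [trainPNN()].
#' @return list with `results` (data.frame: spread, train_acc, test_acc in
#'   percent), `spread` (selected value) and `model` (the selected
#'   [PNNModel-class]).
#' @export
spreadGridSearch <- function(trainScores, trainLabels = NULL,
                             testScores, testLabels = NULL,
                             grid = defaultSpreadGrid(),
                             kernel = c("dot_product", "euclidean")) {
  kernel <- match.arg(kernel)
  if (!length(grid)) stop("empty spread grid")
  grid <- sort(as.numeric(grid))
  res <- data.frame(spread = grid, train_acc = NA_real_, test_acc = NA_real_)
  models <- vector("list", length(grid))
  for (q in seq_along(grid)) {
    mod <- trainPNN(trainScores, trainLabels, spread = grid[q],
                    kernel = kernel)
    res$train_acc[q] <- evaluatePNN(mod, trainScores, trainLabels)$accuracy
    res$test_acc[q] <- evaluatePNN(mod, testScores, testLabels)$accuracy
    models[[q]] <- mod
  }
  ord <- order(-res$train_acc, -res$test_acc, res$spread)
  sel <- ord[1L]
  list(results = res, spread = grid[sel], model = models[[sel]])
}

#' First-n-per-class train/test split indices
#'
#' Splits by stored sample order: the first `nTrain` samples of each class
#' (in their original order) form the training set, the remainder the test
#' set.
#'
#' @param labels per-sample class labels.
#' @param nTrain training samples per class (default 15).
#' @return list with integer index vectors `train` and `test`.
#' @export
trainTestSplit <- function(labels, nTrain = 15L) {
  labels <- as.character(labels)
  idx <- seq_along(labels)
  train <- unlist(lapply(unique(labels), function(cl) {
    w <- idx[labels == cl]
    utils::head(w, nTrain)
  }), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}
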