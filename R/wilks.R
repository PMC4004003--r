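#' @include AllClasses.R
NULL

.scoreInput <- function(scores, labels) {
  if (is(scores, "ScoreMatrix")) {
    if (is.null(labels)) labels <- scores@classLabels
    list(X = scores@scores, labels = labels, ids = scores@componentIds)
  } else {
    X <- as.matrix(scores)
    if (is.null(labels)) stop("labels are required with a plain matrix")
    list(X = X, labels = labels, ids = seq_len(ncol(X)))
  }
}

#' Within-class and total scatter matrices
#'
#' For scores X (samples x m components) with class labels, computes
#'
#' * D (within-class): `d_ij = sum_g sum_k (X[i,g,k] - u[i,g]) (X[j,g,k] - u[j,g])`
#' * A (total):        `a_ij = sum_g sum_k (X[i,g,k] - u[i]) (X[j,g,k] - u[j])`
#'
#' where `u[i,g]` is the class-g mean of component i and `u[i]` the grand
#' mean. In the `"improved"` variant each cross-product is replaced by its
#' absolute value before summation, so deviation products of opposite sign
#' cannot cancel in the off-diagonal entries; diagonals (sums of squares) are
#' unaffected. Since `|xy| = |x||y|`, the improved matrices are crossproducts
#' of the element-wise absolute deviations.
#'
#' @param scores a [ScoreMatrix-class] or numeric samples x m matrix.
#' @param labels class labels (taken from `scores` when it is a
#'   [ScoreMatrix-class]).
#' @param variant `"regular"` or `"improved"`.
#' @return a [ScatterPair-class].
#' @export
scatterMatrices <- function(scores, labels = NULL,
                            variant = c("regular", "improved")) {
  variant <- match.arg(variant)
  inp <- .scoreInput(scores, labels)
  X <- inp$X
  labels <- if (is.factor(inp$labels)) inp$labels else
    factor(inp$labels, levels = unique(as.character(inp$labels)))
  if (ncol(X) < 1L) stop("value error: m = 0 components")
  # a single class is degenerate but well defined: class means equal the
  # grand mean, so D == A and Lambda == 1
  if (any(tabulate(labels, nlevels(labels)) == 0L))
    stop("value error: a class has 0 samples")
  classMeans <- apply(X, 2L, function(col) stats::ave(col, labels))
  classMeans <- matrix(classMeans, nrow = nrow(X))
  Xw <- X - classMeans                       # deviations from class means
  Xt <- sweep(X, 2L, colMeans(X))            # deviations from grand mean
  if (variant == "improved") { Xw <- abs(Xw); Xt <- abs(Xt) }
  new("ScatterPair", D = crossprod(Xw), A = crossprod(Xt),
      variant = variant, componentIds = as.integer(inp$ids))
}

# 2x2 determinant ad - bc evaluated with error compensation
# (Kahan-style: recovers the rounding error of b*c via a split product).
.det2 <- function(M) {
  a <- M[1, 1]; b <- M[1, 2]; cc <- M[2, 1]; d <- M[2, 2]
  w <- b * cc
  e <- .twoProdErr(b, cc, w)
  f <- a * d - w
  f + e
}

# Dekker split product error term: b*c = w + err exactly (up to one fma).
.twoProdErr <- function(b, cc, w) {
  split <- function(x) {
    t <- 134217729 * x            # 2^27 + 1
    hi <- t - (t - x)
    c(hi, x - hi)
  }
  bs <- split(b); cs <- split(cc)
  ((bs[1] * cs[1] - w) + bs[1] * cs[2] + bs[2] * cs[1]) + bs[2] * cs[2]
}

#' Wilks Lambda dispersion ratio
#'
#' `Lambda = det(D) / det(A)`: the ratio of the within-class to the total
#' scatter determinant. Small values indicate well-separated classes. For the
#' regular variant Lambda is always in `[0, 1]`; the improved variant is not
#' bounded above by construction and values above 1 are reported as-is.
#' 2 x 2 determinants use compensated `ad - bc` arithmetic.
#'
#' @param sp a [ScatterPair-class]; or a [ScoreMatrix-class]/matrix, in which
#'   case `labels`/`variant` are forwarded to [scatterMatrices()].
#' @param labels,variant used only when `sp` is not a [ScatterPair-class].
#' @return the non-negative scalar Lambda.
#' @export
wilksLambda <- function(sp, labels = NULL, variant = c("regular", "improved")) {
  if (!is(sp, "ScatterPair"))
    sp <- scatterMatrices(sp, labels, match.arg(variant))
  m <- nrow(sp@A)
  detA <- if (m == 2L) .det2(sp@A) else det(sp@A)
  if (!is.finite(detA) || abs(detA) < 1e-300)
    stop("singularity error: det(A) ~ 0; use fewer components or more samples")
  detD <- if (m == 2L) .det2(sp@D) else det(sp@D)
  detD / detA
}

#' Select the minimising pair from a precomputed ratio table
#'
#' Pure selection stage of the pair search: given a table of dispersion
#' ratios for unordered component pairs, returns the arg-min. Ties are broken
#' to the lexicographically lowest (i, j). Selection always uses the table
#' values at full precision.
#'
#' @param table data.frame with columns `i`, `j`, `lambda` (one row per
#'   unordered pair, i < j).
#' @return list with `pair` (integer 2-vector) and `value`.
#' @export
selectBestPair <- function(table) {
  need <- c("i", "j", "lambda")
  if (!all(need %in% names(table)))
    stop("table must have columns i, j, lambda")
  if (!nrow(table)) stop("empty ratio table")
  ord <- order(table$lambda, table$i, table$j)
  best <- table[ord[1L], ]
  list(pair = as.integer(c(best$i, best$j)), value = as.numeric(best$lambda))
}

#' Exhaustive Wilks Lambda search over component subsets
#'
#' Computes the dispersion ratio for every unordered pair (i, j), i < j, of
#' the available components (or every k-subset for `m = 3`) and selects the
#' minimum. For pairs, all 2 x 2 determinants are derived from a single pair
#' of full scatter matrices, since the (i, j) sub-block of D and A only
#' involves entries (i, i), (j, j) and (i, j).
#'
#' @param scores a [ScoreMatrix-class] or numeric samples x p matrix.
#' @param labels class labels (taken from a [ScoreMatrix-class] input).
#' @param variant `"regular"` or `"improved"`.
#' @param m subset size, 2 (default) or 3.
#' @return a [WilksReport-class]; for `m = 3` the table gains a `k` column
#'   and `bestPair` has length 3.
#' @export
pairSearch <- function(scores, labels = NULL,
                       variant = c("regular", "improved"), m = 2L) {
  variant <- match.arg(variant)
  m <- as.integer(m)
  if (!m %in% c(2L, 3L)) stop("subset search supports m = 2 or 3")
  inp <- .scoreInput(scores, labels)
  p <- ncol(inp$X)
  if (p < m) stop("at least ", m, " components are required")
  sp <- scatterMatrices(scores, labels, variant)
  ids <- sp@componentIds
  if (m == 2L) {
    combos <- utils::combn(p, 2L)
    lam <- apply(combos, 2L, function(ij) {
      sub <- new("ScatterPair",
                 D = sp@D[ij, ij], A = sp@A[ij, ij],
                 variant = variant, componentIds = ids[ij])
      wilksLambda(sub)
    })
    tb <- data.frame(i = ids[combos[1L, ]], j = ids[combos[2L, ]],
                     lambda = lam)
    tb <- tb[order(tb$i, tb$j), , drop = FALSE]
    rownames(tb) <- NULL
    best <- selectBestPair(tb)
    new("WilksReport", table = tb, variant = variant,
        bestPair = best$pair, bestValue = best$value)
  } else {
    combos <- utils::combn(p, 3L)
    lam <- apply(combos, 2L, function(ijk) {
      sub <- new("ScatterPair",
                 D = sp@D[ijk, ijk], A = sp@A[ijk, ijk],
                 variant = variant, componentIds = ids[ijk])
      wilksLambda(sub)
    })
    tb <- data.frame(i = ids[combos[1L, ]], j = ids[combos[2L, ]],
                     k = ids[combos[3L, ]], lambda = lam)
    tb <- tb[order(tb$i, tb$j, tb$k), , drop = FALSE]
    rownames(tb) <- NULL
    ord <- order(tb$lambda, tb$i, tb$j, tb$k)
    best <- tb[ord[1L], ]
    new("WilksReport", table = tb, variant = variant,
        bestPair = as.integer(c(best$i, best$j, best$k)),
        bestValue = as.numeric(best$lambda))
  }
}
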