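#' @include AllClasses.R
NULL

#' Class centroids and pooled within-class covariance
#'
#' Per-class arithmetic mean points of 2-component scores, plus the pooled
#' within-class covariance
#' `S_p = sum_g sum_k (x_gk - c_g)(x_gk - c_g)' / (N - c)`,
#' the covariance that whitens the subsequent centroid Mahalanobis distances.
#' Pooling (rather than a global or per-class covariance) is the standard
#' discriminant-analysis choice and keeps distances comparable across
#' component pairs.
#'
#' @param scores a [ScoreMatrix-class] restricted to 2 components, or a
#'   numeric samples x 2 matrix.
#' @param labels class labels (taken from a [ScoreMatrix-class] input);
#'   every class needs >= 2 samples.
#' @return a [CentroidSet-class].
#' @export
classCentroids <- function(scores, labels = NULL) {
  inp <- .scoreInput(scores, labels)
  X <- inp$X
  if (ncol(X) != 2L)
    stop("centroids are defined on a 2-component score space")
  labels <- if (is.factor(inp$labels)) inp$labels else
    factor(inp$labels, levels = unique(as.character(inp$labels)))
  cnt <- tabulate(labels, nlevels(labels))
  if (any(cnt < 2L))
    stop("insufficient data: every class needs >= 2 samples for the pooled covariance")
  cls <- levels(labels)
  cent <- rbind(
    tapply(X[, 1L], labels, mean)[cls],
    tapply(X[, 2L], labels, mean)[cls]
  )
  cent <- t(cent)
  rownames(cent) <- cls
  colnames(cent) <- NULL
  Xc <- X - cent[as.integer(labels), , drop = FALSE]
  pooled <- crossprod(Xc) / (nrow(X) - length(cls))
  new("CentroidSet", centroids = cent, pooledCov = unname(pooled),
      classes = cls)
}

#' Pairwise Mahalanobis distances between class centroids
#'
#' `MD(g, h) = sqrt((c_g - c_h)' S_p^{-1} (c_g - c_h))` for every unordered
#' class pair, using the pooled within-class covariance `S_p`. Larger
#' distances indicate better-separated classes in the chosen component pair.
#'
#' @param cs a [CentroidSet-class] with invertible pooled covariance.
#' @param regularize if TRUE, add `1e-12 * trace(S_p)` to the diagonal when
#'   `S_p` is numerically singular instead of failing.
#' @return symmetric classes x classes matrix of distances, zero diagonal.
#' @export
pairwiseMahalanobis <- function(cs, regularize = FALSE) {
  stopifnot(is(cs, "CentroidSet"))
  S <- cs@pooledCov
  d2 <- .det2(S)
  if (!is.finite(d2) || abs(d2) < 1e-300 * max(1, max(abs(S))^2)) {
    if (regularize) {
      S <- S + diag(2L) * 1e-12 * sum(diag(S))
    } else {
      stop("singularity error: pooled covariance is singular; ",
           "consider regularize = TRUE (adds 1e-12 * trace to the diagonal)")
    }
  }
  Sinv <- solve(S)
  C <- cs@centroids
  g <- nrow(C)
  out <- matrix(0, g, g, dimnames = list(cs@classes, cs@classes))
  for (a in seq_len(g - 1L)) {
    for (b in seq((a + 1L), g)) {
      dv <- C[a, ] - C[b, ]
      out[a, b] <- out[b, a] <- sqrt(max(0, sum(dv * (Sinv %*% dv))))
    }
  }
  out
}
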