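test_that("centroids and pooled covariance match hand enumeration", {
  # class A: (0,0), (2,2); class B: (4,0), (6,2)
  X <- rbind(c(0, 0), c(2, 2), c(4, 0), c(6, 2))
  lab <- c("A", "A", "B", "B")
  cs <- classCentroids(X, lab)
  expect_equal(cs@centroids, rbind(c(1, 1), c(5, 1)), ignore_attr = TRUE)
  # each class contributes deviations (+-1, +-1): SS = diag-free 2x2 of 4s
  expect_equal(cs@pooledCov, matrix(c(4, 4, 4, 4) / (4 - 2), 2, 2),
               ignore_attr = TRUE)

  # a class of identical points contributes nothing to the pooled covariance
  X2 <- rbind(c(1, 2), c(1, 2), c(0, 0), c(2, 2))
  cs2 <- classCentroids(X2, c("A", "A", "B", "B"))
  expect_equal(cs2@centroids[1, ], c(1, 2), ignore_attr = TRUE)
  expect_equal(cs2@pooledCov, crossprod(rbind(c(-1, -1), c(1, 1))) / 2,
               ignore_attr = TRUE)

  # the grand mean is the sample-size-weighted mean of class centroids
  withr::local_seed(21)
  rs <- randomScores(3, c(4), 2)
  cs3 <- classCentroids(rs$X, rs$labels)
  w <- as.numeric(table(factor(rs$labels, levels = cs3@classes)))
  expect_equal(colSums(cs3@centroids * w) / sum(w), colMeans(rs$X),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(classCentroids(X[1:3, ], c("A", "A", "B")),
               "insufficient data")
})

test_that("Mahalanobis distances reduce to known closed forms", {
  cs <- new("CentroidSet", centroids = rbind(c(0, 0), c(2, 1)),
            pooledCov = diag(c(4, 1)), classes = c("A", "B"))
  md <- pairwiseMahalanobis(cs)
  expect_equal(md["A", "B"], sqrt(2^2 / 4 + 1^2 / 1))
  expect_equal(md["A", "B"],
               sqrt(drop(t(c(2, 1)) %*% solve(diag(c(4, 1))) %*% c(2, 1))))
  expect_equal(diag(md), c(A = 0, B = 0))

  # identical centroids -> zero distance
  cs0 <- new("CentroidSet", centroids = rbind(c(1, 1), c(1, 1)),
             pooledCov = diag(2), classes = c("A", "B"))
  expect_equal(pairwiseMahalanobis(cs0)["A", "B"], 0)

  # identity covariance -> Euclidean distance
  csE <- new("CentroidSet", centroids = rbind(c(0, 0), c(3, 4)),
             pooledCov = diag(2), classes = c("A", "B"))
  expect_equal(pairwiseMahalanobis(csE)["A", "B"], 5)

  # singular pooled covariance errors unless regularised
  csS <- new("CentroidSet", centroids = rbind(c(0, 0), c(1, 1)),
             pooledCov = matrix(1, 2, 2), classes = c("A", "B"))
  expect_error(pairwiseMahalanobis(csS), "singularity")
  expect_true(is.finite(pairwiseMahalanobis(csS, regularize = TRUE)["A", "B"]))
})

test_that("MD is invariant under joint invertible affine maps", {
  withr::local_seed(22)
  for (rep in 1:10) {
    rs <- randomScores(3, 5, 2)
    M <- matrix(rnorm(4), 2, 2)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(4), 2, 2)
    b <- rnorm(2)
    md1 <- pairwiseMahalanobis(classCentroids(rs$X, rs$labels))
    Xt <- sweep(rs$X %*% M, 2, b, `+`)
    md2 <- pairwiseMahalanobis(classCentroids(Xt, rs$labels))
    expect_equal(md1, md2, tolerance = 1e-8)
  }
})

test_that("centroid distances satisfy the triangle inequality", {
  withr::local_seed(23)
  for (rep in 1:10) {
    rs <- randomScores(4, 4, 2)
    md <- pairwiseMahalanobis(classCentroids(rs$X, rs$labels))
    g <- nrow(md)
    for (a in 1:g) for (b in 1:g) for (cc in 1:g)
      expect_lte(md[a, b], md[a, cc] + md[cc, b] + 1e-10)
  }
})

test_that("mean pairwise MD grows with injected class separation", {
  levels <- c(0.5, 1, 1.5, 2, 2.5)
  meanMD <- vapply(levels, function(s) {
    base <- seq(1.6, 3.4, length.out = 10)
    theta <- matrix(rep(base, each = 6), 6, 10)
    for (col in 1:3)
      theta[, col] <- theta[, col] + s * 0.05 * (seq_len(6) - 1)
    cfg <- synthConfig(theta = theta, withinSd = 0.05, noiseSd = 0.01,
                       seed = 99L)
    ds <- simulateENose(cfg)
    fm <- extractFeatures(ds)
    sm <- pcaTransform(fitPCA(fm), fm)
    md <- pairwiseMahalanobis(
      classCentroids(selectComponents(sm, c(1, 2))))
    mean(md[upper.tri(md)])
  }, numeric(1))
  expect_true(all(diff(meanMD) >= 0))
})
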