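test_that("degenerate class structure gives the expected scatter matrices", {
  # samples identical to their class mean: D = 0 in both variants
  X <- rbind(c(1, 2), c(1, 2), c(5, -1), c(5, -1))
  lab <- c("A", "A", "B", "B")
  for (v in c("regular", "improved")) {
    sp <- scatterMatrices(X, lab, v)
    expect_equal(sp@D, matrix(0, 2, 2), ignore_attr = TRUE)
  }
  # one class only: class mean is the grand mean, so D = A exactly
  withr::local_seed(6)
  X1 <- matrix(rnorm(20), 10, 2)
  sp1 <- scatterMatrices(X1, rep("only", 10), "regular")
  expect_equal(sp1@D, sp1@A, tolerance = 1e-12)
  expect_equal(wilksLambda(sp1), 1, tolerance = 1e-12)
})

test_that("scatter matrices and Lambda match the double-loop oracle (hand case)", {
  X <- rbind(c(1.0, 2.0), c(2.0, 1.0), c(3.0, 3.5),
             c(-1.0, 0.5), c(0.0, -2.0), c(1.5, 0.0))
  lab <- rep(c("A", "B"), each = 3)
  for (v in c("regular", "improved")) {
    sp <- scatterMatrices(X, lab, v)
    oc <- oracleScatter(X, lab, v)
    expect_equal(sp@D, oc$D, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sp@A, oc$A, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(wilksLambda(sp), oracleLambda(X, lab, v),
                 tolerance = 1e-12)
  }
})

test_that("Lambda edge cases: identical matrices, zero D, singular A", {
  sp <- new("ScatterPair", D = diag(c(2, 3)), A = diag(c(2, 3)),
            variant = "regular", componentIds = c(1L, 2L))
  expect_equal(wilksLambda(sp), 1)
  sp0 <- new("ScatterPair", D = matrix(0, 2, 2), A = diag(2),
             variant = "regular", componentIds = c(1L, 2L))
  expect_equal(wilksLambda(sp0), 0)
  spS <- new("ScatterPair", D = matrix(0, 2, 2), A = matrix(0, 2, 2),
             variant = "regular", componentIds = c(1L, 2L))
  expect_error(wilksLambda(spS), "singularity")
})

test_that("pair search handles two components and breaks ties lexicographically", {
  withr::local_seed(8)
  rs <- randomScores(3, 5, 2)
  rep2 <- pairSearch(rs$X, rs$labels)
  expect_equal(nrow(wilksTable(rep2)), 1L)
  expect_equal(bestPair(rep2)$pair, c(1L, 2L))

  tbl <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    lambda = c(0.5, 0.2, 0.2))
  expect_equal(selectBestPair(tbl)$pair, c(1L, 3L))
  expect_equal(selectBestPair(tbl)$value, 0.2)
})

test_that("regular Lambda lies in [0, 1] and improved 2x2 determinants are non-negative", {
  withr::local_seed(9)
  for (rep in 1:40) {
    rs <- randomScores(sample(2:4, 1), sample(3:6, 1), sample(2:3, 1))
    lam <- wilksLambda(rs$X, rs$labels, "regular")
    expect_gte(lam, 0)
    expect_lte(lam, 1 + 1e-12)
    if (ncol(rs$X) == 2) {
      sp <- scatterMatrices(rs$X, rs$labels, "improved")
      expect_gte(det(sp@D), -1e-12 * max(sp@D)^2)
      expect_gte(det(sp@A), -1e-12 * max(sp@A)^2)
    }
  }
})

test_that("Lambda is invariant to per-component scaling and sample permutation", {
  withr::local_seed(10)
  rs <- randomScores(3, 6, 3)
  for (v in c("regular", "improved")) {
    lam <- wilksLambda(rs$X, rs$labels, v)
    scaled <- rs$X %*% diag(c(3.2, 0.07, 11))
    expect_equal(wilksLambda(scaled, rs$labels, v), lam, tolerance = 1e-9)
    perm <- sample(nrow(rs$X))
    expect_equal(wilksLambda(rs$X[perm, ], rs$labels[perm], v), lam,
                 tolerance = 1e-9)
  }
})

test_that("variants coincide when all cross-product terms share one sign", {
  # y = 2x makes every deviation product a positive multiple of a square
  withr::local_seed(12)
  x <- rnorm(12)
  X <- cbind(x, 2 * x)
  lab <- rep(c("A", "B"), 6)
  spr <- scatterMatrices(X, lab, "regular")
  spi <- scatterMatrices(X, lab, "improved")
  expect_equal(spr@D, spi@D, tolerance = 1e-12)
  expect_equal(spr@A, spi@A, tolerance = 1e-12)
})

test_that("the exhaustive m = 3 subset search works and agrees with the oracle", {
  withr::local_seed(14)
  rs <- randomScores(3, 8, 4)
  rep3 <- pairSearch(rs$X, rs$labels, variant = "regular", m = 3)
  tb <- wilksTable(rep3)
  expect_equal(nrow(tb), choose(4, 3))
  row <- tb[tb$i == 1 & tb$j == 2 & tb$k == 4, ]
  expect_equal(row$lambda,
               oracleLambda(rs$X[, c(1, 2, 4)], rs$labels, "regular"),
               tolerance = 1e-10)
})

test_that("scatter matrix preconditions are enforced", {
  expect_error(scatterMatrices(matrix(numeric(0), 4, 0), rep("A", 4)),
               "m = 0")
  withr::local_seed(15)
  X <- matrix(rnorm(8), 4, 2)
  lab <- factor(c("A", "A", "B", "B"), levels = c("A", "B", "C"))
  expect_error(scatterMatrices(X, lab), "0 samples")
})
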