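test_that("a PNN stores one pattern neuron per training sample", {
  withr::local_seed(31)
  rs <- randomScores(6, 15, 2)
  mod <- trainPNN(rs$X, rs$labels, spread = 4e-5)
  expect_equal(nrow(mod@patterns), 90L)
  expect_equal(sqrt(rowSums(mod@patterns^2)), rep(1, 90),
               tolerance = 1e-12)

  singletons <- trainPNN(diag(6) + 1, paste0("c", 1:6), spread = 0.1)
  expect_equal(nrow(singletons@patterns), 6L)

  expect_error(trainPNN(rs$X, rs$labels, spread = 0), "spread")
  expect_error(trainPNN(rbind(c(0, 0), c(1, 1)), c("A", "B"), spread = 1),
               "zero-norm")
})

test_that("tiny spreads reproduce the training pattern's class", {
  withr::local_seed(32)
  rs <- randomScores(3, 4, 2)
  mod <- trainPNN(rs$X, rs$labels, spread = 1e-6)
  pr <- predict(mod, rs$X[5, ])
  expect_equal(as.character(pr$class), rs$labels[5])
})

test_that("euclidean-kernel class scores match a two-term hand calculation", {
  mod <- trainPNN(matrix(c(0, 1), ncol = 1), c("A", "B"), spread = 0.5,
                  kernel = "euclidean", normalize = FALSE)
  q <- 0.2
  la <- c(-(q - 0)^2, -(q - 1)^2) / (2 * 0.5^2)
  expected <- exp(la - max(la))   # reported activations are max-rescaled
  pr <- predict(mod, matrix(q, 1, 1))
  expect_equal(as.numeric(pr$activations), expected, tolerance = 1e-12)
  expect_equal(as.character(pr$class), "A")
})

test_that("exact ties resolve to the lower class index and are flagged", {
  mod <- trainPNN(matrix(c(1, -1), ncol = 1), c("B", "A"),
                  spread = 0.3, kernel = "euclidean", normalize = FALSE)
  pr <- predict(mod, matrix(0, 1, 1))
  expect_true(pr$tie[1])
  expect_equal(as.character(pr$class), "B")  # class index 1 = first seen
})

test_that("confusion accuracy arithmetic is exact", {
  expect_equal(confusionAccuracy(diag(5L) * 2L), 100)
  m <- diag(c(5, 4, 5, 5, 3, 5))
  m[2, 5] <- 1; m[5, 3] <- 2
  expect_equal(confusionAccuracy(m), 90)
  expect_error(confusionAccuracy(matrix(1, 2, 3)), "square")
})

test_that("evaluatePNN builds a consistent confusion matrix", {
  withr::local_seed(33)
  rs <- randomScores(3, 10, 2, sd = 0.05, sep = 3)
  split <- trainTestSplit(rs$labels, nTrain = 7)
  mod <- trainPNN(rs$X[split$train, ], rs$labels[split$train], spread = 0.1)
  ev <- evaluatePNN(mod, rs$X[split$test, ], rs$labels[split$test])
  expect_equal(sum(ev$confusion), length(split$test))
  expect_equal(rowSums(ev$confusion),
               c(c1 = 3, c2 = 3, c3 = 3), ignore_attr = TRUE)
  expect_equal(ev$accuracy, 100 * sum(diag(ev$confusion)) / 9)
  expect_error(evaluatePNN(mod, rs$X[1:2, ], c("c1", "zz")), "unseen")
})

test_that("the spread grid search applies the joint-maximum selection rule", {
  expect_equal(defaultSpreadGrid(), seq(1e-5, 1e-4, by = 1e-5))

  withr::local_seed(34)
  rs <- randomScores(3, 10, 2, sd = 1e-3, sep = 1)   # cleanly separable
  split <- trainTestSplit(rs$labels, nTrain = 7)
  gs1 <- spreadGridSearch(rs$X[split$train, ], rs$labels[split$train],
                          rs$X[split$test, ], rs$labels[split$test],
                          grid = 0.05)
  expect_equal(gs1$spread, 0.05)

  gs <- spreadGridSearch(rs$X[split$train, ], rs$labels[split$train],
                         rs$X[split$test, ], rs$labels[split$test],
                         grid = c(1e-5, 1e-4))
  expect_equal(gs$results$train_acc, c(100, 100))
  expect_equal(gs$results$test_acc, c(100, 100))
  expect_equal(gs$spread, 1e-5)   # smallest among the jointly best
})

test_that("spread -> 0 matches 1-nearest-neighbour in the matched metric", {
  withr::local_seed(35)
  for (rep in 1:10) {
    rs <- randomScores(3, 4, 3)
    q <- rnorm(3)
    modC <- trainPNN(rs$X, rs$labels, spread = 1e-7)
    expect_equal(as.character(predict(modC, q)$class),
                 oracleNN(rs$X, rs$labels, q, "cosine"))
    modE <- trainPNN(rs$X, rs$labels, spread = 1e-7, kernel = "euclidean",
                     normalize = FALSE)
    expect_equal(as.character(predict(modE, q)$class),
                 oracleNN(rs$X, rs$labels, q, "euclidean"))
  }
})

test_that("spread -> Inf class scores converge to class pattern counts", {
  withr::local_seed(36)
  rs <- randomScores(3, c(4), 2)
  lab <- c(rep("c1", 4), rep("c2", 4), rep("c3", 4))
  mod <- trainPNN(rs$X, lab, spread = 1e6)
  pr <- predict(mod, rnorm(2))
  expect_equal(as.numeric(pr$activations), c(4, 4, 4), tolerance = 1e-6)
})

test_that("activations stay in (0, 1] and training order never matters", {
  withr::local_seed(37)
  rs <- randomScores(4, 5, 2)
  # at a moderate spread every activation is strictly inside (0, 1], so
  # class sums are positive and bounded by the class pattern counts
  mod <- trainPNN(rs$X, rs$labels, spread = 0.5)
  Q <- matrix(rnorm(10), 5, 2)
  pr <- predict(mod, Q)
  expect_true(all(pr$activations > 0))
  expect_true(all(pr$activations <= 5))
  # at tiny spreads distant classes underflow to exactly 0, never below
  tiny <- predict(trainPNN(rs$X, rs$labels, spread = 2e-5), Q)
  expect_true(all(tiny$activations >= 0))
  expect_true(all(apply(tiny$activations, 1, max) > 0))
  pr1 <- predict(trainPNN(rs$X, rs$labels, spread = 2e-5), Q)
  perm <- sample(nrow(rs$X))
  mod2 <- trainPNN(rs$X[perm, ], rs$labels[perm], spread = 2e-5)
  pr2 <- predict(mod2, Q)
  expect_equal(as.character(pr1$class), as.character(pr2$class))
})

test_that("the ordered split takes the first n of each class", {
  lab <- rep(c("A", "B"), each = 20)
  sp <- trainTestSplit(lab, nTrain = 15)
  expect_equal(sp$train, c(1:15, 21:35))
  expect_equal(sp$test, c(16:20, 36:40))
})
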