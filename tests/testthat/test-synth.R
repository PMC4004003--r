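test_that("the generator has the documented shape and reproducibility contract", {
  cfg <- synthConfig(seed = 77L)
  ds <- simulateENose(cfg)
  expect_equal(nSamples(ds), 120L)
  expect_equal(nSensors(ds), 10L)
  expect_equal(nTimePoints(ds), 80L)
  expect_equal(length(classNames(ds)), 6L)
  ds2 <- simulateENose(cfg)
  expect_identical(ds@responses, ds2@responses)
  ds3 <- simulateENose(synthConfig(seed = 78L))
  expect_false(identical(ds@responses, ds3@responses))
})

test_that("noise-free curves follow the closed-form kinetics exactly", {
  cfg <- synthConfig(nClasses = 2, nPerClass = 3, nSensors = 4, nTime = 20,
                     tau = 5, withinSd = 0, noiseSd = 0, seed = 1L)
  ds <- simulateENose(cfg)
  # all samples of a class are identical
  expect_equal(responseCurve(ds, 1), responseCurve(ds, 3))
  fm <- extractFeatures(ds)
  expected <- expectedDave(cfg@theta, tau = 5, nTime = 20, dt = 1)
  for (g in 1:2) {
    row <- which(as.integer(classLabels(ds)) == g)[1]
    expect_equal(featureValues(fm)[row, ], expected[g, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("empirical class D_ave means approach the closed form as noise shrinks", {
  for (ns in c(0.02, 0.002)) {
    cfg <- synthConfig(nClasses = 2, nPerClass = 40, nSensors = 3,
                       nTime = 80, tau = 10, withinSd = 0.01,
                       noiseSd = ns, seed = 5L)
    ds <- simulateENose(cfg)
    fm <- extractFeatures(ds)
    expected <- expectedDave(cfg@theta, 10, 80, 1)
    tol <- 4 * sqrt(2 * ns^2 / 79^2 + (0.01 * 0.0115)^2) / sqrt(40)
    for (g in 1:2) {
      rows <- as.integer(classLabels(ds)) == g
      expect_equal(colMeans(featureValues(fm)[rows, ]), expected[g, ],
                   tolerance = max(tol / max(abs(expected[g, ])), 1e-8),
                   ignore_attr = TRUE)
    }
  }
})

test_that("between-class scatter grows with asymptote separation", {
  trace_between <- vapply(c(0.5, 1, 2), function(s) {
    theta <- matrix(2, 3, 4)
    theta[, 1] <- 2 + s * 0.1 * (0:2)
    cfg <- synthConfig(nClasses = 3, nPerClass = 10, nSensors = 4,
                       nTime = 40, theta = theta, withinSd = 0.02,
                       noiseSd = 0.005, seed = 9L)
    fm <- extractFeatures(simulateENose(cfg))
    sp <- scatterMatrices(featureValues(fm), classLabels(fm), "regular")
    sum(diag(sp@A - sp@D))
  }, numeric(1))
  expect_true(all(diff(trace_between) > 0))
})

test_that("the hidden-discriminant scenario hides the signal off the top components", {
  ds <- enoseScenario("hidden_discriminant", seed = 7L)
  fm <- extractFeatures(ds)
  model <- fitPCA(fm)
  sm <- pcaTransform(model, fm)

  rep <- pairSearch(sm, variant = "improved")
  expect_false(all(bestPair(rep)$pair == c(1L, 2L)))

  # class-mean differences projected on PC1 are negligible relative to the
  # within-class spread along PC1
  s1 <- scoreValues(selectComponents(sm, 1))[, 1]
  lab <- classLabels(sm)
  classMeans <- tapply(s1, lab, mean)
  withinSd <- sqrt(mean(tapply(s1, lab, var)))
  expect_lt(max(classMeans) - min(classMeans), withinSd)

  # the selected pair classifies; the default pair does not
  split <- trainTestSplit(lab, 15)
  accOn <- function(pc) {
    s2 <- scoreValues(selectComponents(sm, pc))
    gs <- spreadGridSearch(s2[split$train, ], lab[split$train],
                           s2[split$test, ], lab[split$test])
    evaluatePNN(gs$model, s2[split$test, ], lab[split$test])$accuracy
  }
  expect_gt(accOn(bestPair(rep)$pair), accOn(c(1L, 2L)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nTime = 1), "2 time points")
  expect_error(synthConfig(noiseSd = -1), "non-negative")
  expect_error(synthConfig(theta = matrix(-1, 6, 10)), "positive")
})
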