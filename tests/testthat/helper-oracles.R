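# Independent oracles, written as literal translations of the defining
# formulas (explicit loops, no shared code with the implementation).

# Scatter matrices by explicit double-loop enumeration over classes and
# samples, term by term.
oracleScatter <- function(X, labels, variant) {
  labels <- as.character(labels)
  cls <- unique(labels)
  m <- ncol(X)
  D <- matrix(0, m, m)
  A <- matrix(0, m, m)
  grand <- colMeans(X)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      for (g in cls) {
        rows <- which(labels == g)
        ui_g <- mean(X[rows, i])
        uj_g <- mean(X[rows, j])
        for (k in rows) {
          dterm <- (X[k, i] - ui_g) * (X[k, j] - uj_g)
          aterm <- (X[k, i] - grand[i]) * (X[k, j] - grand[j])
          if (variant == "improved") {
            dterm <- abs(dterm)
            aterm <- abs(aterm)
          }
          D[i, j] <- D[i, j] + dterm
          A[i, j] <- A[i, j] + aterm
        }
      }
    }
  }
  list(D = D, A = A)
}

# Lambda from the oracle scatter matrices via base determinants.
oracleLambda <- function(X, labels, variant) {
  sc <- oracleScatter(X, labels, variant)
  det(sc$D) / det(sc$A)
}

# D_ave by the literal summation formula.
oracleDave <- function(x, dt) {
  n <- length(x)
  s <- 0
  for (z in seq_len(n - 1)) s <- s + (x[z + 1] - x[z]) / dt
  s / (n - 1)
}

# Characteristic-polynomial roots of a symmetric matrix via the companion
# matrix route: build the monic characteristic polynomial coefficients by
# expansion over permutations (small p only), then call polyroot().
oracleEigenvalues <- function(S) {
  p <- nrow(S)
  stopifnot(p <= 3)
  if (p == 2) {
    coefs <- c(S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1],
               -(S[1, 1] + S[2, 2]), 1)
  } else {
    tr <- sum(diag(S))
    m2 <- (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]) +
          (S[1, 1] * S[3, 3] - S[1, 3] * S[3, 1]) +
          (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2])
    d3 <- S[1, 1] * (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2]) -
          S[1, 2] * (S[2, 1] * S[3, 3] - S[2, 3] * S[3, 1]) +
          S[1, 3] * (S[2, 1] * S[3, 2] - S[2, 2] * S[3, 1])
    # det(S - x I) = -x^3 + tr x^2 - m2 x + d3 ; negate for monic
    coefs <- c(-d3, m2, -tr, 1)
  }
  sort(Re(polyroot(coefs)), decreasing = TRUE)
}

# Brute-force 1-nearest-neighbour classifier in a chosen metric.
oracleNN <- function(train, labels, q, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  labels <- as.character(labels)
  if (metric == "cosine") {
    train <- train / sqrt(rowSums(train^2))
    q <- q / sqrt(sum(q^2))
  }
  d <- sqrt(rowSums(sweep(train, 2, q)^2))
  labels[which.min(d)]
}

# Small random labelled dataset in score space for property tests.
randomScores <- function(nClasses, perClass, m, sd = 1, sep = 1) {
  centers <- matrix(rnorm(nClasses * m, 0, sep), nClasses, m)
  X <- do.call(rbind, lapply(seq_len(nClasses), function(g) {
    sweep(matrix(rnorm(perClass * m, 0, sd), perClass, m), 2,
          centers[g, ], `+`)
  }))
  list(X = X, labels = rep(paste0("c", seq_len(nClasses)), each = perClass))
}

# Small random ENoseDataset for IO round-trip property tests.
randomDataset <- function(nClasses = 2, perClass = 2, nSensors = 3,
                          nTime = 4, dt = 1) {
  n <- nClasses * perClass
  arr <- array(runif(nSensors * nTime * n, 0.5, 3),
               dim = c(nSensors, nTime, n))
  ENoseDataset(arr, sprintf("s%02d", seq_len(n)),
               rep(paste0("cl", seq_len(nClasses)), each = perClass),
               dt = dt)
}
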