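test_that("perfect correlation and anticorrelation hit the bounds", {
  x <- rnorm(6)
  R <- matrix(c(x, 2 * x + 3, -x, rnorm(6)), 6, 4)
  L <- groupCorrelation(R)
  W <- layerWeights(L)
  expect_equal(W[1, 2], 1.0)
  expect_equal(W[1, 3], -1.0)
  expect_equal(diag(W), rep(0, 4))
  expect_identical(W, t(W))
})

test_that("production correlations match the brute-force pairwise oracle", {
  # fixed small instance
  X <- matrix(c(2.1, 3.4, 1.2, 5.5, 4.1,
                0.3, 0.9, 1.8, 0.5, 1.1,
                7.2, 6.1, 6.8, 7.9, 6.5,
                1.0, 2.0, 1.5, 0.8, 2.2), 5, 4)
  expect_lt(max(abs(layerWeights(groupCorrelation(X)) - brutePearson(X))),
            1e-12)
  # random instances
  set.seed(7)
  for (i in 1:5) {
    Y <- matrix(rnorm(60), 10, 6)
    expect_lt(max(abs(layerWeights(groupCorrelation(Y)) - brutePearson(Y))),
              1e-12)
  }
})

test_that("zero-variance regions are rejected by name", {
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- 4
  expect_error(groupCorrelation(X), "zero-variance region.*b")
  expect_error(groupCorrelation(X[1:2, ]), ">= 3 subjects")
})

test_that("density thresholding keeps exactly round(d * E) edges", {
  set.seed(3)
  W <- matrix(0, 5, 5); up <- upper.tri(W)
  W[up] <- runif(sum(up), 0.05, 1); W <- W + t(W)
  A <- thresholdBinarize(W, 0.4)
  expect_identical(sum(A) / 2, 4)  # round(0.4 * 10)
  for (d in c(0.15, 0.5, 0.85)) {
    A <- thresholdBinarize(W, d)
    expect_identical(sum(A) / 2, floor(d * 10 + 0.5))
  }
  # with too few positive weights the quota is truncated, never padded
  Wneg <- W; Wneg[Wneg > 0.3] <- -Wneg[Wneg > 0.3]
  npos <- sum(Wneg[up] > 0)
  expect_identical(sum(thresholdBinarize(Wneg, 0.9)) / 2, as.numeric(npos))
  expect_error(thresholdBinarize(W, 0), "in \\(0, 1\\)")
  expect_error(thresholdBinarize(W, 1.2), "in \\(0, 1\\)")
})

test_that("equal weights break ties by lexicographic (i, j) edge order", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  A <- thresholdBinarize(W, 0.5)  # round(0.5 * 6) = 3 edges
  expect_identical(sum(A) / 2, 3)
  # the first three pairs in (i, j) lexicographic order: 1-2, 1-3, 1-4
  expect_identical(A[1, 2] + A[1, 3] + A[1, 4], 3)
  expect_identical(sum(A[2:4, 2:4]), 0)
})

test_that("absolute mode keeps weights above d, negatives removed first", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.9; W[1, 3] <- 0.5; W[1, 4] <- 0.3; W[2, 3] <- -0.8
  W <- W + t(W)
  A <- thresholdBinarize(W, 0.4, mode = "absolute")
  expect_identical(sum(A) / 2, 2)
  expect_identical(A[1, 2], 1); expect_identical(A[1, 3], 1)
  expect_identical(A[2, 3], 0)  # |-0.8| > d but negatives are dropped
  # density mode also never selects a negative edge
  Ad <- thresholdBinarize(W, 0.9, mode = "density")
  expect_identical(Ad[2, 3], 0)
})

test_that("density sweeps are nested: edges at d1 < d2 are a subset", {
  set.seed(11)
  W <- matrix(0, 12, 12); up <- upper.tri(W)
  W[up] <- runif(sum(up), -0.5, 1); W <- W + t(W)
  sweep <- seq(0.4, 0.7, by = 0.05)
  prev <- thresholdBinarize(W, sweep[1])
  for (d in sweep[-1]) {
    cur <- thresholdBinarize(W, d)
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
})

test_that("supra-adjacency has layers on diagonal and coupling off it", {
  A1 <- matrix(0, 3, 3); A1[1, 2] <- A1[2, 1] <- 1
  A2 <- matrix(0, 3, 3); A2[2, 3] <- A2[3, 2] <- 1
  net <- buildSupra(list(CTH = A1, FDG = A2), couplingStrength = 1)
  W <- supraAdjacency(net)
  expect_identical(dim(W), c(6L, 6L))
  expect_equal(W[1:3, 1:3], A1)
  expect_equal(W[4:6, 4:6], A2)
  expect_equal(W[1:3, 4:6], diag(3))
  expect_identical(W, t(W))

  # empty layers give the pure coupling structure
  Z <- matrix(0, 3, 3)
  Wz <- supraAdjacency(buildSupra(list(a = Z, b = Z), couplingStrength = 2))
  expect_equal(Wz, rbind(cbind(Z, 2 * diag(3)), cbind(2 * diag(3), Z)))

  # random layers come back bit-identical from the diagonal blocks
  set.seed(5)
  B1 <- randomLayer(8); B2 <- randomLayer(8)
  Wb <- supraAdjacency(buildSupra(list(x = B1, y = B2)))
  expect_identical(Wb[1:8, 1:8], B1)
  expect_identical(Wb[9:16, 9:16], B2)

  expect_error(buildSupra(list(a = Z, b = matrix(0, 4, 4))), "differ in size")
})

test_that("region relabeling permutes all downstream results consistently", {
  set.seed(21)
  n <- 7
  X1 <- matrix(rnorm(12 * n), 12, n); X2 <- matrix(rnorm(12 * n), 12, n)
  perm <- sample(n)
  measuresOf <- function(Xa, Xb) {
    bin <- lapply(list(Xa, Xb), function(X)
      thresholdBinarize(groupCorrelation(X), 0.5))
    multiplexMeasures(buildSupra(bin, threshold = 0.5))
  }
  m0 <- measuresOf(X1, X2)
  mp <- measuresOf(X1[, perm], X2[, perm])
  expect_equal(mp$nodal$o, m0$nodal$o[perm])
  expect_equal(mp$nodal$p, m0$nodal$p[perm])
  expect_equal(mp$global_mpc, m0$global_mpc)
  expect_equal(mp$global_overlapping_degree, m0$global_overlapping_degree)
})
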