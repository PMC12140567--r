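completeGraph <- function(n) { A <- matrix(1, n, n); diag(A) <- 0; A }

test_that("degrees, overlapping degree, and MPC on closed-form graphs", {
  # empty layers: everything zero
  Z <- matrix(0, 4, 4)
  net0 <- buildSupra(list(CTH = Z, FDG = Z))
  expect_equal(unname(intralayerDegrees(net0)), matrix(0, 4, 2))
  expect_equal(overlappingDegree(net0)$nodal, rep(0, 4))
  expect_equal(overlappingDegree(net0)$global, 0)
  expect_equal(unname(nodalMPC(net0)), rep(0, 4))  # o = 0 defined as p = 0

  # complete layers: k = n - 1 everywhere, o = 2(n - 1), balanced p = 1
  K4 <- completeGraph(4)
  net1 <- buildSupra(list(CTH = K4, FDG = K4))
  expect_equal(unname(intralayerDegrees(net1)), matrix(3, 4, 2))
  K5 <- completeGraph(5)
  net2 <- buildSupra(list(CTH = K5, FDG = K5))
  expect_equal(overlappingDegree(net2)$nodal, rep(8, 5))
  expect_equal(overlappingDegree(net2)$global, 8)
  expect_equal(unname(nodalMPC(net2)), rep(1, 5))
  expect_equal(globalMPC(net2), 1)
})

test_that("MPC evaluates the participation formula exactly", {
  # node degrees (3, 1): p = 2 (1 - (9/16 + 1/16)) = 0.75
  A1 <- matrix(0, 5, 5)
  A1[1, 2] <- A1[1, 3] <- A1[1, 4] <- 1; A1 <- A1 + t(A1)  # k1 = 3
  A2 <- matrix(0, 5, 5)
  A2[1, 5] <- 1; A2 <- A2 + t(A2)                          # k2 = 1
  p <- nodalMPC(buildSupra(list(CTH = A1, FDG = A2)))
  expect_equal(unname(p[1]), 0.75)

  # single-layer node: p = 0; balanced node: p = 1
  pz <- nodalMPC(buildSupra(list(CTH = A1, FDG = matrix(0, 5, 5))))
  expect_equal(unname(pz[1]), 0)
  pb <- nodalMPC(buildSupra(list(CTH = A1, FDG = A1)))
  expect_equal(unname(pb[1]), 1)
})

test_that("M = 2 MPC equals the closed form 4 k1 k2 / (k1 + k2)^2", {
  set.seed(9)
  for (i in 1:10) {
    L1 <- randomLayer(8); L2 <- randomLayer(8, 0.6)
    net <- buildSupra(list(a = L1, b = L2))
    K <- intralayerDegrees(net)
    o <- rowSums(K)
    want <- ifelse(o > 0, 4 * K[, 1] * K[, 2] / o^2, 0)
    expect_equal(unname(nodalMPC(net)), unname(want), tolerance = 1e-12)
  }
})

test_that("degrees match a brute-force neighbour count", {
  set.seed(14)
  L1 <- randomLayer(6); L2 <- randomLayer(6)
  K <- intralayerDegrees(buildSupra(list(a = L1, b = L2)))
  expect_equal(unname(K[, 1]), as.numeric(bruteDegrees(L1)))
  expect_equal(unname(K[, 2]), as.numeric(bruteDegrees(L2)))
})

test_that("measures are symmetric under layer exchange and coupling-free", {
  set.seed(2)
  L1 <- randomLayer(7); L2 <- randomLayer(7)
  n12 <- buildSupra(list(a = L1, b = L2), couplingStrength = 1)
  n21 <- buildSupra(list(b = L2, a = L1), couplingStrength = 1)
  expect_equal(nodalMPC(n12), nodalMPC(n21))
  expect_equal(overlappingDegree(n12)$nodal, overlappingDegree(n21)$nodal)
  # replica coupling is structural: strength never enters the measures
  for (cs in c(0, 0.5, 3)) {
    ncs <- buildSupra(list(a = L1, b = L2), couplingStrength = cs)
    expect_identical(nodalMPC(ncs), nodalMPC(n12))
  }
})

test_that("identical layers give global MPC 1 at every threshold", {
  set.seed(30)
  X <- matrix(rnorm(20 * 8), 20, 8)
  L <- groupCorrelation(X)
  for (d in seq(0.4, 0.7, by = 0.05)) {
    A <- thresholdBinarize(L, d)
    net <- buildSupra(list(CTH = A, FDG = A), threshold = d)
    if (all(rowSums(A) > 0)) expect_equal(globalMPC(net), 1)
    mm <- multiplexMeasures(net)
    expect_equal(mm$nodal$o, mm$nodal$k_CTH + mm$nodal$k_FDG)
    expect_equal(mm$global_mpc, mean(mm$nodal$p))
    expect_equal(mm$global_overlapping_degree, mean(mm$nodal$o))
  }
})

test_that("half balanced, half isolated nodes average to global MPC 0.5", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1   # nodes 1-2 balanced, 3-4 isolated
  net <- buildSupra(list(a = A, b = A))
  expect_equal(unname(nodalMPC(net)), c(1, 1, 0, 0))
  expect_equal(globalMPC(net), 0.5)
})
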