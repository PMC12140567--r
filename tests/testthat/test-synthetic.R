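test_that("identical configs generate identical cohorts", {
  cfg <- generatorConfig(nPerGroup = c(A = 10, B = 10), nRegions = 6, seed = 5)
  g1 <- generateCohort(cfg)
  g2 <- generateCohort(cfg)
  expect_identical(assay(g1$cohort, "CTH"), assay(g2$cohort, "CTH"))
  expect_identical(g1$truth$configKey, g2$truth$configKey)
  # a different seed moves the samples but not the population
  g3 <- generateCohort(generatorConfig(nPerGroup = c(A = 10, B = 10),
                                       nRegions = 6, seed = 6))
  expect_false(identical(assay(g1$cohort, "CTH"), assay(g3$cohort, "CTH")))
  expect_equal(g1$truth$targets, g3$truth$targets)
})

test_that("independence limit: base correlation 0 leaves |r| near 0", {
  n <- 400
  cfg <- generatorConfig(nPerGroup = c(A = n), nRegions = 8,
                         baseCorrelation = 0, seed = 19)
  co <- generateCohort(cfg)$cohort
  R <- layerWeights(groupCorrelation(residualize(co, "CTH")$residuals))
  offdiag <- R[upper.tri(R)]
  expect_lt(mean(abs(offdiag)), 2 / sqrt(n))
})

test_that("mean off-diagonal correlation converges to baseCorrelation", {
  cfg <- generatorConfig(nPerGroup = c(A = 500), nRegions = 34,
                         baseCorrelation = 0.5, seed = 20)
  g <- generateCohort(cfg)
  # the target itself is calibrated to mean 0.5 exactly
  TT <- g$truth$targets$A$CTH
  expect_equal(mean(TT[upper.tri(TT)]), 0.5, tolerance = 1e-10)
  # and the empirical group-level correlations concentrate around it
  R <- layerWeights(groupCorrelation(residualize(g$cohort, "CTH")$residuals))
  expect_lt(abs(mean(R[upper.tri(R)]) - 0.5), 0.05)
})

test_that("single-layer epicenter increments change population nodal MPC", {
  cfg <- generatorConfig(nPerGroup = c(A = 10, B = 10), nRegions = 20,
                         epicenterNodes = 5:8,
                         epicenterDelta = c(CTH = 0.25, FDG = 0), seed = 3)
  g <- generateCohort(cfg)
  popMPC <- function(targets) {
    bin <- lapply(targets, function(S) { diag(S) <- 0; thresholdBinarize(S, 0.5) })
    nodalMPC(buildSupra(bin, threshold = 0.5))
  }
  pA <- popMPC(g$truth$targets$A)
  pB <- popMPC(g$truth$targets$B)
  expect_equal(pA, popMPC(g$truth$targets$A))  # deterministic
  expect_false(isTRUE(all.equal(pB[5:8], pA[5:8])))
  # non-epicenter nodes keep identical target matrices only in layer FDG
  expect_equal(g$truth$targets$A$FDG, g$truth$targets$B$FDG)
})

test_that("infeasible uniform elevations trigger the logged PSD repair", {
  cfg <- generatorConfig(nPerGroup = c(A = 5, B = 5), nRegions = 20,
                         baseCorrelation = 0.3,
                         epicenterNodes = 1:4,
                         epicenterDelta = c(CTH = 0.3, FDG = 0), seed = 1)
  g <- suppressWarnings(generateCohort(cfg))
  expect_true(g$truth$psdRepaired)
  # repaired targets are valid correlation matrices
  S <- g$truth$targets$B$CTH
  expect_equal(diag(S), setNames(rep(1, 20), rownames(S)))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("null pairs share one population and carry the generator key", {
  cfg <- generatorConfig(nPerGroup = c(X = 8, Y = 8), nRegions = 5,
                         epicenterNodes = 1:2,
                         epicenterDelta = c(CTH = 0.2, FDG = -0.2), seed = 9)
  np <- makeNullPair(cfg)
  expect_identical(ncol(np$cohortA), 8L)
  expect_identical(ncol(np$cohortB), 8L)
  # epicenter stripped: both groups get the same target matrices
  expect_equal(np$truth$targets$A, np$truth$targets$B)
  expect_identical(length(np$truth$epicenterNodes), 0L)
  expect_true(nzchar(np$truth$configKey))
})

test_that("planted nodes top the ranking of absolute nodal MPC differences", {
  g <- generateCohort(plantedConfig(seed = 1))
  sp <- splitByGroup(g$cohort, c("A", "B"))
  res <- permutationTest(sp$A, sp$B, "nodal_mpc", d = 0.5, nPerm = 150,
                         seed = 2)
  ranks <- rank(-abs(res$diff))
  # all six planted nodes in the top quartile of 34, most in the top six
  expect_true(all(ranks[15:20] <= 8))
  expect_gte(sum(ranks[15:20] <= 6), 5)
})
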