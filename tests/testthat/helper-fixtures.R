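# shared fixtures and independent brute-force oracles
suppressPackageStartupMessages(library(SummarizedExperiment))

toyAtlas <- function(n = 4) roiAtlas("toy", sprintf("r%02d", seq_len(n)))

# small cohort with hand-settable ROI matrices (subjects x regions input)
toyCohort <- function(cth, fdg = cth, group = "CN",
                      age = seq(55, by = 5, length.out = nrow(cth)),
                      sex = rep_len(c(1, 0), nrow(cth)),
                      education = 8 + (seq_len(nrow(cth)) * 7) %% 11,
                      ids = sprintf("s%02d", seq_len(nrow(cth))),
                      atlas = toyAtlas(ncol(cth))) {
  cov <- data.frame(subject_id = ids, group = group, age = age, sex = sex,
                    education = education)
  cohortTable(list(CTH = t(cth), FDG = t(fdg)), cov, atlas)
}

# textbook Pearson r, one pair at a time
brutePearson <- function(X) {
  n <- ncol(X)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- X[, i]; xj <- X[, j]
    R[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
  }
  R
}

# neighbour-count degrees by explicit loop
bruteDegrees <- function(A) {
  vapply(seq_len(nrow(A)), function(i)
    sum(vapply(seq_len(ncol(A)), function(j) i != j && A[i, j] == 1, TRUE)),
    0L)
}

# Benjamini-Hochberg step-up executed literally: sort, find largest k with
# p_(k) <= q k / m, reject those; adjusted p = min over j >= k of m p_(j) / j
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, m * p[o[k]] / k)
    adj[o[k]] <- min(1, running)
  }
  adj
}

# random symmetric zero-diagonal binary adjacency
randomLayer <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1, p)
  A + t(A)
}

# the planted-effect validation configuration (see methods vignette): a
# strongly covarying system so the sampling noise of r is well below the
# planted increments; FDG suppression -0.3 plus CTH elevation +0.1 on six
# mid-gradient nodes
plantedConfig <- function(seed = 1, nPerGroup = c(A = 60, B = 60))
  generatorConfig(nPerGroup = nPerGroup, nRegions = 34,
                  baseCorrelation = 0.78, correlationSpread = 0.04,
                  epicenterNodes = 15:20,
                  epicenterDelta = c(CTH = 0.1, FDG = -0.3), seed = seed)
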