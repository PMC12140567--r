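# One evaluation of the per-group network pipeline: for each group (rows
# idxA / idxB of the pooled residual matrices), correlate -> zero negatives
# -> binarize -> degrees -> measure; returns statA - statB (vector for nodal
# measures, scalar for global ones). resList: one pooled subjects x regions
# residual matrix per modality; ut: .utIndex(n) precomputed by the caller.
.groupStat <- function(resList, idx, d, mode, ut, n, measure) {
  M <- length(resList)
  K <- matrix(0, n, M)
  for (a in seq_len(M)) {
    w <- stats::cor(resList[[a]][idx, , drop = FALSE])[ut]
    sel <- .selectEdges(w, d, mode)
    K[, a] <- .edgeDegrees(sel, ut, n)
  }
  switch(measure,
    global_mpc = mean(.mpcFromDegrees(K)),
    nodal_mpc = .mpcFromDegrees(K),
    global_overlapping_degree = mean(rowSums(K)),
    stop("unknown measure '", measure, "'"))
}

#' Permutation test of a multiplex measure between two groups
#'
#' Computes the observed group difference (group A minus group B) of a
#' multiplex measure at one threshold, then builds its null distribution by
#' repeatedly reassigning the pooled subjects at random to two pseudo-groups
#' of the original sizes and re-running the entire per-group pipeline
#' (correlation, thresholding, supra-assembly, measure) on each reassignment.
#' Covariate residualization is fitted ONCE on the pooled pair before
#' permuting: the regression does not involve group membership, so refitting
#' inside permutations would reproduce the identical pooled fit.
#'
#' The two-tailed p-value uses the add-one estimator
#' \eqn{p = (\#\{|\Delta_{null}| \ge |\Delta_{obs}|\} + 1)/(n_{perm} + 1)},
#' which is never exactly 0. The 2.5% and 97.5% quantiles of the null are
#' reported alongside. For \code{measure = "nodal_mpc"} one test per region
#' is run and Benjamini-Hochberg adjusted p-values are added across the
#' regions (the FDR family is the set of regions within this one comparison,
#' measure, and threshold).
#'
#' @param cohortA,cohortB \linkS4class{CohortTable}s sharing atlas and
#'   modalities, each with >= 3 subjects.
#' @param measure One of \code{"global_mpc"}, \code{"nodal_mpc"},
#'   \code{"global_overlapping_degree"}.
#' @param d Threshold passed to \code{\link{thresholdBinarize}}.
#' @param mode Threshold mode, \code{"density"} (default) or
#'   \code{"absolute"}.
#' @param nPerm Number of permutations (default 5000; < 100 is refused).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param fdrQ FDR level used for the \code{significant} flag on nodal
#'   results (default 0.05).
#' @return data.frame with columns measure, threshold, node, diff, null_lo,
#'   null_hi, p, p_fdr, significant, n_perm, seed. Global measures have one
#'   row with \code{node = "global"} and \code{p_fdr = NA} (no family).
#' @examples
#' cfg <- generatorConfig(nPerGroup = c(A = 15, B = 15), nRegions = 6,
#'                        seed = 7)
#' cohort <- generateCohort(cfg)$cohort
#' gr <- splitByGroup(cohort, c("A", "B"))
#' permutationTest(gr$A, gr$B, "global_mpc", d = 0.5, nPerm = 200, seed = 1)
#' @export
permutationTest <- function(cohortA, cohortB,
                            measure = c("global_mpc", "nodal_mpc",
                                        "global_overlapping_degree"),
                            d, mode = c("density", "absolute"),
                            nPerm = 5000L, seed = 1L, fdrQ = 0.05) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  stopifnot(is(cohortA, "CohortTable"), is(cohortB, "CohortTable"))
  if (!identical(regions(atlas(cohortA)), regions(atlas(cohortB))) ||
      !identical(modalities(cohortA), modalities(cohortB)))
    stop("cohorts must share atlas regions and modalities")
  nA <- ncol(cohortA); nB <- ncol(cohortB)
  if (nA < 3L || nB < 3L)
    stop("each group needs >= 3 subjects; got ", nA, " and ", nB)
  if (nPerm < 100L)
    stop("nPerm < 100 gives a meaningless null; refusing (got ", nPerm, ")")

  pooled <- .poolPair(cohortA, cohortB)
  resList <- lapply(modalities(pooled), function(m)
    residualize(pooled, m)$residuals)
  names(resList) <- modalities(pooled)

  n <- nRegions(atlas(pooled))
  ut <- .utIndex(n)
  idxA <- seq_len(nA); idxB <- nA + seq_len(nB)
  stat <- function(ia, ib)
    .groupStat(resList, ia, d, mode, ut, n, measure) -
      .groupStat(resList, ib, d, mode, ut, n, measure)

  obs <- stat(idxA, idxB)
  nullMat <- matrix(0, nPerm, length(obs))
  set.seed(seed)
  pool <- seq_len(nA + nB)
  for (b in seq_len(nPerm)) {
    s <- sample.int(nA + nB)
    stopifnot(identical(sort(s), pool))   # relabeling keeps the subject multiset
    nullMat[b, ] <- stat(s[idxA], s[idxB])
  }

  p <- (colSums(abs(nullMat) >= matrix(abs(obs), nPerm, length(obs),
                                       byrow = TRUE)) + 1) / (nPerm + 1)
  qs <- apply(nullMat, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  node <- if (measure == "nodal_mpc") regions(atlas(pooled)) else "global"
  if (measure == "nodal_mpc") {
    adj <- fdrBH(p, q = fdrQ)
    p_fdr <- adj$p_adjusted
    significant <- adj$reject
  } else {
    p_fdr <- NA_real_
    significant <- p <= fdrQ
  }
  data.frame(measure = measure, threshold = d, node = node, diff = obs,
             null_lo = qs[1L, ], null_hi = qs[2L, ], p = p, p_fdr = p_fdr,
             significant = significant, n_perm = as.integer(nPerm),
             seed = as.integer(seed), row.names = NULL)
}

# Pool two cohorts; subject ids are prefixed by position when they collide
# (e.g. self-comparisons in null calibration).
.poolPair <- function(cohortA, cohortB) {
  idA <- colData(cohortA)$subject_id
  idB <- colData(cohortB)$subject_id
  if (length(intersect(idA, idB))) {
    cohortA <- .renameSubjects(cohortA, paste0("A.", idA))
    cohortB <- .renameSubjects(cohortB, paste0("B.", idB))
  }
  bindCohorts(cohortA, cohortB)
}

.renameSubjects <- function(cohort, ids) {
  cov <- as.data.frame(colData(cohort))
  cov$subject_id <- ids
  assayList <- lapply(modalities(cohort), function(m) {
    A <- assay(cohort, m); colnames(A) <- ids; A
  })
  names(assayList) <- modalities(cohort)
  cohortTable(assayList, cov, atlas(cohort))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone enforced) with rejection flags at
#' level \code{q}.
#'
#' @param pValues Numeric vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{p_adjusted} and logical \code{reject}
#'   (\code{p_adjusted <= q}).
#' @export
fdrBH <- function(pValues, q = 0.05) {
  if (!length(pValues)) stop("empty p-value vector")
  if (any(!is.finite(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pValues, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}
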