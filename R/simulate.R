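#' Configuration for the synthetic multimodal cohort generator
#'
#' Describes a population per group: an exchangeable (compound-symmetry)
#' inter-regional correlation background per modality, an optional
#' "epicenter" subset of regions whose incident correlations are raised by a
#' per-modality increment in one group (layer-imbalanced increments create a
#' known nodal-MPC group difference), additive linear age/sex/education
#' effects, and a residual noise scale. Pearson correlation is scale-free, so
#' \code{noiseSd} and the covariate betas only matter for the
#' residualization stage, not for the network topology.
#'
#' @param nPerGroup Named integer vector of group sizes; names are the group
#'   labels (e.g. \code{c(CN = 43, PPA = 43)}).
#' @param nRegions Number of atlas regions (ignored when \code{atlas} is
#'   given).
#' @param modalities Layer labels (default \code{c("CTH", "FDG")}).
#' @param baseCorrelation Mean background inter-regional correlation, in
#'   [0, 1); default 0.3, a typical mean structural-covariance correlation.
#'   0 gives fully independent regions.
#' @param correlationSpread Amplitude of the deterministic node-loading
#'   gradient of the single-factor background (default 0.2). The factor
#'   loadings run from \code{abar - spread} to \code{abar + spread} across
#'   the region order, grading the correlation spectrum the way real
#'   structural-covariance matrices are graded (some region pairs tightly
#'   coupled, others barely), so a density threshold has a well-defined
#'   population topology. 0 gives an equicorrelated (compound-symmetry)
#'   background, in which every edge is population-tied and the thresholded
#'   network is sampling noise.
#' @param epicenterNodes Integer indices (into the region order) of the
#'   planted epicenter; empty for a null configuration.
#' @param epicenterDelta Named numeric, modality -> correlation increment
#'   added to every edge incident to an epicenter node in the affected
#'   group; may differ by layer (layer imbalance). Must keep |r| < 1.
#' @param epicenterGroup Label of the group carrying the epicenter effect
#'   (default: the last group).
#' @param covariateEffects Named list, modality -> numeric c(intercept, age,
#'   sex, education). Defaults emulate cortical thickness in mm and FDG SUVR.
#' @param noiseSd Residual scale of the multivariate draw; scalar or named
#'   per modality (default 1).
#' @param atlas Optional \linkS4class{RoiAtlas}; default a synthetic atlas
#'   with regions \code{lh-r01 ...} / \code{rh-r...} split across
#'   hemispheres.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nPerGroup = c(A = 30, B = 30), nRegions = 34L,
                            modalities = c("CTH", "FDG"),
                            baseCorrelation = 0.3,
                            correlationSpread = 0.2,
                            epicenterNodes = integer(0),
                            epicenterDelta = stats::setNames(
                              rep(0, length(modalities)), modalities),
                            epicenterGroup = names(nPerGroup)[length(nPerGroup)],
                            covariateEffects = NULL,
                            noiseSd = 1, atlas = NULL, seed = 1L) {
  if (is.null(names(nPerGroup)) || any(!nzchar(names(nPerGroup))))
    stop("nPerGroup must be named by group label")
  if (any(nPerGroup < 3L)) stop("each group needs >= 3 subjects")
  if (baseCorrelation < 0 || baseCorrelation >= 1)
    stop("baseCorrelation must be in [0, 1)")
  if (correlationSpread < 0) stop("correlationSpread must be >= 0")
  if (!is.null(atlas)) nRegions <- nRegions(atlas)
  else {
    half <- ceiling(nRegions / 2)
    atlas <- roiAtlas("synthetic",
                      c(sprintf("lh-r%02d", seq_len(half)),
                        sprintf("rh-r%02d", seq_len(nRegions - half))))
  }
  epicenterNodes <- as.integer(epicenterNodes)
  if (length(epicenterNodes) &&
      (any(epicenterNodes < 1L) || any(epicenterNodes > nRegions)))
    stop("epicenterNodes out of range 1..", nRegions)
  epicenterDelta <- epicenterDelta[modalities]
  epicenterDelta[is.na(epicenterDelta)] <- 0
  names(epicenterDelta) <- modalities
  if (any(abs(baseCorrelation + epicenterDelta) >= 1))
    stop("epicenterDelta pushes |r| to 1 or beyond")
  if (is.null(covariateEffects)) {
    # layer 1 on a cortical-thickness-like scale, later layers SUVR-like
    covariateEffects <- lapply(seq_along(modalities), function(a)
      if (a == 1L) c(2.5, -0.02, 0.1, 0.01) else c(1.5, -0.005, 0.05, 0.005))
    names(covariateEffects) <- modalities
  }
  if (!all(modalities %in% names(covariateEffects)))
    stop("covariateEffects must be named by modality")
  if (length(noiseSd) == 1L)
    noiseSd <- stats::setNames(rep(noiseSd, length(modalities)), modalities)
  structure(list(nPerGroup = nPerGroup, nRegions = as.integer(nRegions),
                 modalities = modalities, baseCorrelation = baseCorrelation,
                 correlationSpread = correlationSpread,
                 epicenterNodes = epicenterNodes,
                 epicenterDelta = epicenterDelta,
                 epicenterGroup = epicenterGroup,
                 covariateEffects = covariateEffects,
                 noiseSd = noiseSd, atlas = atlas, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# canonical string form of a config (the "generator hash" recorded in ground
# truth); two configs produce identical cohorts iff their keys match
.configKey <- function(config) {
  flat <- config
  flat$atlas <- c(atlasName(config$atlas), regions(config$atlas))
  paste(deparse(flat, control = "all"), collapse = "")
}

# Background correlation: single-factor model with a deterministic node
# loading gradient, S = a a' off the diagonal, a_i = abar + spread * u_i with
# u_i equally spaced in [-1, 1]. PSD by construction; abar is calibrated so
# the mean off-diagonal correlation equals baseCorrelation exactly. spread = 0
# recovers compound symmetry; spread > 0 grades the correlation spectrum the
# way real structural-covariance matrices are graded, giving the thresholded
# population network a well-defined (hub-gradient) topology instead of a tie.
.backgroundSigma <- function(n, rho, spread) {
  if (rho == 0) return(diag(n))   # independence limit; gradient needs a factor
  u <- seq(-1, 1, length.out = n)
  corrTerm <- spread^2 * sum(u^2) / (n * (n - 1))
  abar <- sqrt(rho + corrTerm)
  a <- abar + spread * u
  if (max(abs(a)) > 1)
    stop("correlationSpread ", spread, " with baseCorrelation ", rho,
         " needs factor loadings > 1; reduce one of them")
  S <- tcrossprod(a)
  diag(S) <- 1
  S
}

# target population correlation matrix for one (group, modality) cell
.targetSigma <- function(config, group, modality) {
  n <- config$nRegions
  rho <- config$baseCorrelation
  S <- .backgroundSigma(n, rho, config$correlationSpread)
  if (group == config$epicenterGroup && length(config$epicenterNodes)) {
    delta <- config$epicenterDelta[[modality]]
    if (delta != 0) {
      e <- config$epicenterNodes
      # every edge incident to an epicenter node gets the increment once
      inc <- outer(seq_len(n) %in% e, seq_len(n) %in% e, "|")
      S[inc] <- S[inc] + delta
      S[S >= 1] <- 1 - 1e-6
      S[S <= -1] <- -(1 - 1e-6)
      diag(S) <- 1
    }
  }
  dimnames(S) <- list(regions(config$atlas), regions(config$atlas))
  .psdRepair(S)
}

# Repair an indefinite target to the nearest correlation matrix (Higham
# alternating projections, eigenvalues floored at 1e-8); flags the repair in
# attr(, "psd_repaired"). Unlike a one-shot eigenvalue clip + rescale, the
# nearest-matrix projection leaves planted correlation increments essentially
# intact.
.psdRepair <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (any(e < tol)) {
    repaired <- TRUE
    S2 <- as.matrix(Matrix::nearPD(S, corr = TRUE, eig.tol = tol,
                                   conv.tol = 1e-10, maxit = 200)$mat)
    dimnames(S2) <- dimnames(S)
    S <- (S2 + t(S2)) / 2
  }
  attr(S, "psd_repaired") <- repaired
  S
}

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Per subject: age ~ U(50, 80), sex ~ Bernoulli(0.5), education ~ U(8, 22);
#' per modality, the ROI vector is the covariate linear term plus
#' \code{noiseSd} times a multivariate normal draw whose correlation is the
#' group's target matrix. Group-level Pearson networks computed from the
#' residuals therefore converge to the target correlation structure, which
#' is returned as ground truth together with the epicenter node list.
#'
#' @param config A \code{\link{generatorConfig}}.
#' @return List with \code{cohort} (one \linkS4class{CohortTable} holding all
#'   groups) and \code{truth}: \code{targets[[group]][[modality]]} population
#'   correlation matrices, \code{epicenterNodes}, \code{epicenterGroup},
#'   \code{configKey}, \code{psdRepaired} flag.
#' @examples
#' g <- generateCohort(generatorConfig(nPerGroup = c(CN = 10, PPA = 10),
#'                                     nRegions = 8, seed = 42))
#' g$cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  n <- config$nRegions
  targets <- lapply(names(config$nPerGroup), function(g) {
    out <- lapply(config$modalities, .targetSigma, config = config, group = g)
    names(out) <- config$modalities
    out
  })
  names(targets) <- names(config$nPerGroup)
  psdRepaired <- any(vapply(targets, function(tg)
    any(vapply(tg, attr, TRUE, "psd_repaired")), TRUE))

  pieces <- list()
  for (g in names(config$nPerGroup)) {
    ng <- config$nPerGroup[[g]]
    cov <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(ng)), group = g,
      age = stats::runif(ng, 50, 80),
      sex = stats::rbinom(ng, 1, 0.5),
      education = stats::runif(ng, 8, 22))
    X <- cbind(1, cov$age, cov$sex, cov$education)
    assayList <- lapply(config$modalities, function(m) {
      E <- MASS::mvrnorm(ng, mu = rep(0, n), Sigma = targets[[g]][[m]])
      # same covariate effect for every region; recycles down the columns
      Y <- drop(X %*% config$covariateEffects[[m]]) + config$noiseSd[[m]] * E
      t(Y)  # regions x subjects
    })
    names(assayList) <- config$modalities
    pieces[[g]] <- cohortTable(assayList, cov, config$atlas)
  }
  cohort <- do.call(bindCohorts, unname(pieces))
  list(cohort = cohort,
       truth = list(targets = targets,
                    epicenterNodes = config$epicenterNodes,
                    epicenterGroup = config$epicenterGroup,
                    configKey = .configKey(config),
                    psdRepaired = psdRepaired))
}

#' Two cohorts drawn from one identical population
#'
#' Strips any epicenter effect from \code{config} and draws two groups
#' (labels \code{A} and \code{B}) from the same population -- the input for
#' type-I-error calibration of \code{\link{permutationTest}}.
#'
#' @param config A \code{\link{generatorConfig}}; only the sizes of its
#'   first two groups are used (recycled if it has one).
#' @return List with \code{cohortA}, \code{cohortB}, and \code{truth}
#'   (including the shared \code{configKey}).
#' @export
makeNullPair <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  sizes <- config$nPerGroup
  if (length(sizes) == 1L) sizes <- rep(sizes, 2L)
  nullCfg <- generatorConfig(
    nPerGroup = stats::setNames(sizes[1:2], c("A", "B")),
    nRegions = config$nRegions, modalities = config$modalities,
    baseCorrelation = config$baseCorrelation,
    correlationSpread = config$correlationSpread,
    covariateEffects = config$covariateEffects,
    noiseSd = config$noiseSd, atlas = config$atlas, seed = config$seed)
  g <- generateCohort(nullCfg)
  sp <- splitByGroup(g$cohort, c("A", "B"))
  list(cohortA = sp$A, cohortB = sp$B, truth = g$truth)
}
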