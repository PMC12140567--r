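#' Remove age, sex, and education effects from each region
#'
#' Fits, for every atlas region, the ordinary least-squares model
#' \deqn{Y_i = \beta_0 + \beta_1 Age + \beta_2 Sex + \beta_3 Education + \epsilon_i}
#' across all subjects in \code{cohort}, and returns the residuals
#' \eqn{\epsilon_i} that downstream network construction consumes. The fit is
#' a QR decomposition of the shared design matrix, so each region costs one
#' back-substitution. Fitting is intended to run on the pooled sample of the
#' groups being compared (see \code{\link{permutationTest}}), which keeps
#' subjects exchangeable under the permutation null.
#'
#' @param cohort A \linkS4class{CohortTable} with at least 5 subjects.
#' @param modality Which assay to residualize; default the first.
#' @return List with elements \code{residuals} (subjects x regions matrix;
#'   column means ~ 0, columns orthogonal to every covariate) and
#'   \code{coefficients} (data.frame region, beta0, beta_age, beta_sex,
#'   beta_education).
#' @examples
#' cohort <- generateCohort(generatorConfig(nPerGroup = c(A = 20, B = 20),
#'                                          nRegions = 6, seed = 1))$cohort
#' r <- residualize(cohort, "CTH")
#' colMeans(r$residuals)  # ~ 0
#' @export
residualize <- function(cohort, modality = modalities(cohort)[1]) {
  stopifnot(is(cohort, "CohortTable"))
  if (!modality %in% modalities(cohort))
    stop("unknown modality '", modality, "'")
  cd <- colData(cohort)
  n <- nrow(cd)
  if (n < 5L)
    stop("residualization needs >= 5 subjects (4 model parameters); got ", n)
  X <- cbind(`(Intercept)` = 1, age = cd$age, sex = cd$sex,
             education = cd$education)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- t(assay(cohort, modality))          # subjects x regions
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  coefs <- data.frame(region = colnames(Y),
                      beta0 = beta["(Intercept)", ],
                      beta_age = beta["age", ],
                      beta_sex = beta["sex", ],
                      beta_education = beta["education", ],
                      row.names = NULL)
  list(residuals = res, coefficients = coefs)
}

#' Residualize every modality of a cohort
#'
#' Convenience wrapper around \code{\link{residualize}} returning a new
#' \linkS4class{CohortTable} whose assays hold the residuals (same dimensions
#' and subject order; covariates unchanged).
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @return A \linkS4class{CohortTable} of residuals.
#' @export
residualizeCohort <- function(cohort) {
  assayList <- lapply(modalities(cohort), function(m)
    t(residualize(cohort, m)$residuals))
  names(assayList) <- modalities(cohort)
  cohortTable(assayList, as.data.frame(colData(cohort)), atlas(cohort))
}
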