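#' Assemble a CohortTable from in-memory pieces
#'
#' @param assayList Named list (one element per modality) of numeric matrices,
#'   either regions x subjects or subjects x regions (auto-oriented against
#'   the atlas size; regions x subjects wins on ambiguity).
#' @param covariates data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{sex}, \code{education}. Textual sex (\code{"M"}/
#'   \code{"F"}) is recoded to 1/0.
#' @param atlas A \linkS4class{RoiAtlas}; matrix rows are matched (and if
#'   necessary reordered) to its region order.
#' @return A \linkS4class{CohortTable}.
#' @examples
#' a <- roiAtlas("toy", c("r1", "r2", "r3"))
#' m <- matrix(rnorm(9), 3, 3, dimnames = list(regions(a), paste0("s", 1:3)))
#' cov <- data.frame(subject_id = paste0("s", 1:3), group = "CN",
#'                   age = c(60, 65, 70), sex = c(1, 0, 1), education = 12)
#' cohortTable(list(CTH = m), cov, a)
#' @export
cohortTable <- function(assayList, covariates, atlas) {
  stopifnot(is(atlas, "RoiAtlas"), is.list(assayList), length(assayList) >= 1L)
  if (is.null(names(assayList)) || any(!nzchar(names(assayList))))
    stop("assayList must be named by modality")
  covariates <- .coerceCovariates(covariates)
  n <- nRegions(atlas)
  oriented <- lapply(names(assayList), function(m) {
    A <- as.matrix(assayList[[m]])
    if (nrow(A) != n && ncol(A) == n) A <- t(A)
    if (nrow(A) != n)
      stop("modality '", m, "': matrix does not match atlas size ", n)
    if (is.null(rownames(A))) rownames(A) <- regions(atlas)
    miss <- setdiff(regions(atlas), rownames(A))
    if (length(miss))
      stop("modality '", m, "': missing region column(s): ",
           paste(miss, collapse = ", "))
    A <- A[regions(atlas), , drop = FALSE]
    if (is.null(colnames(A))) colnames(A) <- covariates$subject_id
    storage.mode(A) <- "double"
    A
  })
  names(oriented) <- names(assayList)
  se <- SummarizedExperiment(
    assays = oriented,
    colData = DataFrame(covariates, row.names = covariates$subject_id))
  metadata(se)$atlas <- atlas
  new("CohortTable", se)
}

.coerceCovariates <- function(cov) {
  cov <- as.data.frame(cov, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(need, colnames(cov))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
  cov$subject_id <- as.character(cov$subject_id)
  cov$group <- as.character(cov$group)
  if (is.character(cov$sex) || is.factor(cov$sex)) {
    s <- toupper(substr(as.character(cov$sex), 1, 1))
    bad <- !s %in% c("M", "F", "0", "1")
    if (any(bad))
      stop("unrecognized sex code(s): ",
           paste(unique(cov$sex[bad]), collapse = ", "),
           " (accepted: M, F, 0, 1)")
    num <- rep(NA_real_, length(s))
    num[s == "M"] <- 1; num[s == "F"] <- 0
    num[s %in% c("0", "1")] <- as.numeric(s[s %in% c("0", "1")])
    cov$sex <- num
    attr(cov, "sex_coding") <- c(M = 1, F = 0)
  }
  for (v in c("age", "sex", "education")) {
    cov[[v]] <- as.numeric(cov[[v]])
    if (any(!is.finite(cov[[v]])))
      stop("non-numeric or missing value in covariate '", v, "'")
  }
  cov[, need]
}

.readDelim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read a multi-modal ROI cohort from delimited text files
#'
#' One file per modality; TSV or CSV is chosen by file extension. Each file
#' has one row per subject with columns \code{subject_id}, \code{group},
#' \code{age}, \code{sex}, \code{education} followed by one column per atlas
#' region (any order; columns are restored to the canonical atlas order).
#' All modality files must contain exactly the same subjects with identical
#' covariates. Missing cells are rejected, never imputed.
#'
#' @param modalityPaths Named character vector or list, modality -> file path.
#' @param atlas A \linkS4class{RoiAtlas}.
#' @return A validated \linkS4class{CohortTable}.
#' @seealso \code{\link{writeCohort}} for the inverse operation.
#' @export
readCohort <- function(modalityPaths, atlas) {
  stopifnot(length(modalityPaths) >= 1L)
  modalityPaths <- unlist(modalityPaths)
  if (is.null(names(modalityPaths)) || any(!nzchar(names(modalityPaths))))
    stop("modalityPaths must be named by modality")
  covCols <- c("subject_id", "group", "age", "sex", "education")
  covRef <- NULL
  assayList <- list()
  for (m in names(modalityPaths)) {
    path <- modalityPaths[[m]]
    if (!file.exists(path)) stop("modality '", m, "': file not found: ", path)
    tab <- .readDelim(path)
    miss <- setdiff(covCols, colnames(tab))
    if (length(miss))
      stop("modality '", m, "': missing covariate column(s): ",
           paste(miss, collapse = ", "))
    missReg <- setdiff(regions(atlas), colnames(tab))
    if (length(missReg))
      stop("modality '", m, "': missing region column(s): ",
           paste(missReg, collapse = ", "))
    if (anyDuplicated(tab$subject_id))
      stop("modality '", m, "': duplicate subject_id: ",
           paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
             collapse = ", "))
    cov <- .coerceCovariates(tab[, covCols])
    if (is.null(covRef)) covRef <- cov
    else {
      extra <- setdiff(cov$subject_id, covRef$subject_id)
      lost <- setdiff(covRef$subject_id, cov$subject_id)
      if (length(extra) || length(lost))
        stop("modality '", m, "': subject set differs from '",
             names(modalityPaths)[1], "' (missing: ",
             paste(lost, collapse = ", "), "; extra: ",
             paste(extra, collapse = ", "), ")")
      cov <- cov[match(covRef$subject_id, cov$subject_id), ]
      if (!isTRUE(all.equal(covRef[, c("age", "sex", "education")],
                            cov[, c("age", "sex", "education")],
                            check.attributes = FALSE)) ||
          !identical(covRef$group, cov$group))
        stop("modality '", m, "': covariates disagree with '",
             names(modalityPaths)[1], "'")
      tab <- tab[match(covRef$subject_id, tab$subject_id), ]
    }
    vals <- tab[, regions(atlas), drop = FALSE]
    num <- vapply(vals, is.numeric, TRUE)
    if (!all(num))
      stop("modality '", m, "': non-numeric ROI column(s): ",
           paste(regions(atlas)[!num], collapse = ", "))
    M <- t(as.matrix(vals))
    if (!all(is.finite(M)))
      stop("modality '", m, "': missing or non-finite ROI value(s)")
    colnames(M) <- covRef$subject_id
    assayList[[m]] <- M
  }
  cohortTable(assayList, covRef, atlas)
}

#' Write a CohortTable back to one delimited file per modality
#'
#' Produces files \code{readCohort} can re-read; values round-trip
#' bit-identically (written with full precision, \code{digits = 17}).
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @param modalityPaths Named vector modality -> output path; names must
#'   equal \code{modalities(cohort)}. Extension picks TSV/CSV.
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, modalityPaths) {
  stopifnot(is(cohort, "CohortTable"))
  modalityPaths <- unlist(modalityPaths)
  if (!setequal(names(modalityPaths), modalities(cohort)))
    stop("modalityPaths names must equal modalities(cohort)")
  cd <- as.data.frame(colData(cohort))
  for (m in names(modalityPaths)) {
    path <- modalityPaths[[m]]
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    vals <- t(assay(cohort, m))
    out <- cbind(cd[, c("subject_id", "group", "age", "sex", "education")],
                 as.data.frame(vals, check.names = FALSE))
    # 17 significant digits preserve doubles exactly
    for (j in seq_along(out))
      if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(modalityPaths)
}

#' Partition a cohort by group label
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @param groupLabels Character vector of group labels to extract; every
#'   label must be present in the cohort.
#' @return Named list of \linkS4class{CohortTable}, one per requested label.
#' @export
splitByGroup <- function(cohort, groupLabels) {
  stopifnot(is(cohort, "CohortTable"))
  have <- unique(colData(cohort)$group)
  unknown <- setdiff(groupLabels, have)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (cohort has: ", paste(have, collapse = ", "), ")")
  out <- lapply(groupLabels, function(g)
    cohort[, colData(cohort)$group == g])
  names(out) <- groupLabels
  out
}

#' Concatenate cohorts sharing an atlas and modalities
#'
#' @param ... \linkS4class{CohortTable} objects.
#' @return A single \linkS4class{CohortTable}.
#' @export
bindCohorts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "CohortTable")))
  a0 <- atlas(xs[[1]])
  m0 <- modalities(xs[[1]])
  for (x in xs[-1])
    if (!identical(regions(atlas(x)), regions(a0)) ||
        !identical(modalities(x), m0))
      stop("cohorts must share atlas regions and modalities")
  ids <- unlist(lapply(xs, function(x) colData(x)$subject_id))
  if (anyDuplicated(ids))
    stop("duplicate subject_id across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  assayList <- lapply(m0, function(m)
    do.call(cbind, lapply(xs, assay, m)))
  names(assayList) <- m0
  cov <- do.call(rbind, lapply(xs, function(x)
    as.data.frame(colData(x))[, c("subject_id", "group", "age", "sex",
                                  "education")]))
  cohortTable(assayList, cov, a0)
}

#' @rdname CohortTable-class
#' @export
setMethod("atlas", "CohortTable", function(x) metadata(x)$atlas)

#' @rdname CohortTable-class
#' @export
setMethod("modalities", "CohortTable", function(x) assayNames(x))

#' @rdname CohortTable-class
#' @export
setMethod("groups", "CohortTable", function(x)
  as.character(unique(colData(x)$group)))

setMethod("show", "CohortTable", function(object) {
  cd <- colData(object)
  cat("CohortTable:", ncol(object), "subjects x", nrow(object),
      "regions (", atlasName(atlas(object)), ")\n")
  cat("  modalities:", paste(modalities(object), collapse = ", "), "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(cd$group)),
                                 as.integer(table(cd$group))),
                         collapse = ", "), "\n")
})
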