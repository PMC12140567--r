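#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' RoiAtlas: an ordered brain parcellation
#'
#' Holds the canonical, ordered list of region identifiers for one cortical
#' parcellation (e.g. the 68-region Desikan-Killiany atlas). Every matrix the
#' package derives is indexed by this order; input tables with permuted region
#' columns are reordered to it on read.
#'
#' @slot name Single label for the atlas (e.g. \code{"DK68"}).
#' @slot regions Character vector of unique, hemisphere-prefixed region
#'   identifiers (\code{"lh-entorhinal"}); the order is canonical.
#' @slot lobe Character vector parallel to \code{regions} with a coarse lobe
#'   tag (frontal, temporal, parietal, occipital, cingulate, insula) used by
#'   \code{\link{reportRegions}}. May contain \code{NA}.
#'
#' @seealso \code{\link{dkAtlas}}, \code{\link{destrieuxAtlas}}
#' @export
setClass("RoiAtlas",
  representation(name = "character", regions = "character", lobe = "character"))

setValidity("RoiAtlas", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@regions) < 2L)
    msg <- c(msg, "an atlas needs at least 2 regions")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "region identifiers must be unique")
  if (length(object@lobe) != length(object@regions))
    msg <- c(msg, "'lobe' must be parallel to 'regions'")
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-subject covariates plus multi-modal ROI values
#'
#' A \linkS4class{SummarizedExperiment} whose assays are the modality
#' matrices (regions in rows, subjects in columns; one assay per modality,
#' e.g. \code{"CTH"} in mm and \code{"FDG"} as SUVR) and whose \code{colData}
#' carries \code{subject_id}, \code{group}, \code{age}, \code{sex} (numeric
#' 0/1), and \code{education}. The \linkS4class{RoiAtlas} lives in
#' \code{metadata(x)$atlas}; row order always equals the atlas region order.
#'
#' @seealso \code{\link{readCohort}}, \code{\link{generateCohort}}
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  atlas <- metadata(object)$atlas
  if (!is(atlas, "RoiAtlas"))
    return("metadata(x)$atlas must be a RoiAtlas")
  if (!identical(rownames(object), regions(atlas)))
    msg <- c(msg, "row order must equal the atlas region order")
  if (length(assays(object)) < 1L)
    msg <- c(msg, "at least one modality assay is required")
  if (is.null(assayNames(object)) || anyDuplicated(assayNames(object)))
    msg <- c(msg, "assays must carry unique modality names")
  need <- c("subject_id", "group", "age", "sex", "education")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    cd <- colData(object)
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "duplicate subject_id")
    if (any(!is.finite(cd$age)) || any(cd$age < 0))
      msg <- c(msg, "age must be finite and >= 0")
    if (any(!is.finite(cd$education)) || any(cd$education < 0))
      msg <- c(msg, "education must be finite and >= 0")
    for (m in assayNames(object))
      if (!all(is.finite(assay(object, m))))
        msg <- c(msg, paste0("non-finite value in modality '", m, "'"))
  }
  if (length(msg)) msg else TRUE
})

#' LayerMatrix: one group-level weighted correlation layer
#'
#' Symmetric matrix of Pearson correlations between all region pairs,
#' computed across the subjects of one group from residualized values of one
#' modality. The diagonal is defined as 0 (self-connections excluded).
#'
#' @slot weights Symmetric numeric matrix, off-diagonal entries in [-1, 1],
#'   zero diagonal; dimnames are region identifiers.
#' @slot modality Modality label (e.g. \code{"CTH"}).
#' @slot group Group label the layer was computed from.
#' @slot nSubjects Number of subjects behind the correlations.
#'
#' @seealso \code{\link{groupCorrelation}}, \code{\link{thresholdBinarize}}
#' @export
setClass("LayerMatrix",
  representation(weights = "matrix", modality = "character",
                 group = "character", nSubjects = "integer"))

setValidity("LayerMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  else {
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
      msg <- c(msg, "weights must be symmetric")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be 0")
    off <- w[row(w) != col(w)]
    if (any(!is.finite(off)) || any(abs(off) > 1 + 1e-12))
      msg <- c(msg, "off-diagonal weights must be finite and in [-1, 1]")
  }
  if (length(object@nSubjects) != 1L || object@nSubjects < 3L)
    msg <- c(msg, "nSubjects must be a single count >= 3")
  if (length(msg)) msg else TRUE
})

#' MultiplexNetwork: binarized layers coupled into a supra-adjacency matrix
#'
#' A multiplex network on a shared node set: one binary, symmetric,
#' zero-diagonal adjacency matrix per layer, plus diagonal replica coupling
#' C = couplingStrength * I. The supra-adjacency matrix W places the layers
#' on its diagonal blocks and C on the off-diagonal blocks (M = 2 layers
#' gives a 2n x 2n W).
#'
#' @slot layers Named list of binary adjacency matrices, one per modality.
#' @slot couplingStrength Scalar weight of the replica (interlayer) edges.
#' @slot threshold The threshold d the layers were binarized at.
#' @slot thresholdMode \code{"density"} or \code{"absolute"}.
#' @slot supra The assembled (M n) x (M n) supra-adjacency matrix.
#'
#' @seealso \code{\link{buildSupra}}, \code{\link{multiplexMeasures}}
#' @export
setClass("MultiplexNetwork",
  representation(layers = "list", couplingStrength = "numeric",
                 threshold = "numeric", thresholdMode = "character",
                 supra = "matrix"))

setValidity("MultiplexNetwork", function(object) {
  msg <- character()
  L <- object@layers
  if (length(L) < 2L) msg <- c(msg, "a multiplex network needs >= 2 layers")
  ns <- vapply(L, nrow, 0L)
  if (length(unique(ns)) != 1L)
    msg <- c(msg, "all layers must share the same node set")
  for (A in L) {
    if (!all(A %in% c(0, 1))) { msg <- c(msg, "layers must be binary"); break }
    if (!identical(A, t(A)))  { msg <- c(msg, "layers must be symmetric"); break }
    if (any(diag(A) != 0))    { msg <- c(msg, "layer diagonals must be 0"); break }
  }
  n <- unname(ns[1])
  if (!length(msg) && !all(dim(object@supra) == n * length(L)))
    msg <- c(msg, "supra matrix has wrong dimensions")
  if (length(msg)) msg else TRUE
})
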