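# Upper-triangle index pairs in (i, j) lexicographic order (i < j, sorted by
# i then j) -- the canonical edge order used for deterministic tie-breaking.
.utIndex <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  cbind(i = i, j = j)
}

# round half away from zero (round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Select retained edges from an upper-triangle weight vector (lexicographic
# edge order). Negative weights are removed first and can never become edges,
# so in density mode the edge count is min(round(d * E), number of positive
# weights). Density mode keeps the m = roundHalfAway(d * E) strongest edges
# with stable (-w, i, j) tie-break; absolute mode keeps w > d.
.selectEdges <- function(w, d, mode) {
  if (mode == "density") {
    m <- as.integer(.roundHalfAway(d * length(w)))
    if (m == 0L) return(integer(0))
    # order() is stable, and w is already in lexicographic edge order
    sel <- order(-w)[seq_len(m)]
    sort(sel[w[sel] > 0])
  } else {
    which(w > d)
  }
}

# degrees of the binarized graph directly from the selected edge subset
.edgeDegrees <- function(sel, ut, n) {
  tabulate(c(ut[sel, 1L], ut[sel, 2L]), nbins = n)
}

#' Group-level correlation layer from residualized values
#'
#' Computes the Pearson correlation between every pair of regions across the
#' subjects of one group -- the weighted adjacency of one layer of the
#' multiplex network (e.g. \eqn{A^{CTH}} or \eqn{A^{FDG}}). The diagonal
#' (self-connections) is set to 0.
#'
#' @param residuals Subjects x regions numeric matrix, normally the
#'   \code{residuals} element of \code{\link{residualize}} restricted to one
#'   group's subjects.
#' @param modality Label stored on the layer.
#' @param group Group label stored on the layer.
#' @return A \linkS4class{LayerMatrix}.
#' @export
groupCorrelation <- function(residuals, modality = "layer", group = "group") {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 3L)
    stop("group correlation needs >= 3 subjects; got ", nrow(residuals))
  sds <- apply(residuals, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(residuals)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  W <- stats::cor(residuals)
  diag(W) <- 0
  new("LayerMatrix", weights = W, modality = modality, group = group,
      nSubjects = nrow(residuals))
}

#' @rdname LayerMatrix-class
#' @export
setMethod("layerWeights", "LayerMatrix", function(x) x@weights)

setMethod("show", "LayerMatrix", function(object) {
  cat("LayerMatrix '", object@modality, "' (group ", object@group, "): ",
      nrow(object@weights), " regions, n = ", object@nSubjects,
      " subjects\n", sep = "")
})

#' Binarize a weighted layer at a threshold
#'
#' Negative correlations are removed (set to 0) before either rule is
#' applied. In \code{"density"} mode the \code{round(d * n(n-1)/2)} strongest
#' edges are retained (half rounded away from zero; ties broken by descending
#' weight, then ascending (i, j) lexicographic edge order, so the result is
#' platform-independent). In \code{"absolute"} mode an edge is kept iff its
#' weight exceeds \code{d}.
#'
#' @param layer A \linkS4class{LayerMatrix}, or a plain symmetric weight
#'   matrix with zero diagonal.
#' @param d Threshold in (0, 1): an edge density or an absolute correlation.
#' @param mode \code{"density"} (default) or \code{"absolute"}.
#' @return Binary symmetric adjacency matrix with zero diagonal (dimnames
#'   preserved).
#' @export
thresholdBinarize <- function(layer, d, mode = c("density", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d >= 1)
    stop("threshold d must be a single value in (0, 1); got ", d)
  W <- if (is(layer, "LayerMatrix")) layerWeights(layer) else as.matrix(layer)
  n <- nrow(W)
  ut <- .utIndex(n)
  sel <- .selectEdges(W[ut], d, mode)
  A <- matrix(0, n, n, dimnames = dimnames(W))
  if (length(sel)) {
    A[ut[sel, , drop = FALSE]] <- 1
    A[ut[sel, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Assemble a multiplex network's supra-adjacency matrix
#'
#' Stacks the binarized layers into the block supra-adjacency matrix
#' \deqn{W = \begin{pmatrix} A^{(1)} & C \\ C & A^{(2)} \end{pmatrix}}
#' with replica coupling \eqn{C = c I}: each node is linked only to its own
#' copy in the other layers (the multiplex topology the participation
#' coefficient presumes). For M layers W is (M n) x (M n) with C on every
#' off-diagonal block.
#'
#' @param layers Named list (>= 2) of binary symmetric adjacency matrices of
#'   equal size, e.g. from \code{\link{thresholdBinarize}}.
#' @param couplingStrength Scalar c >= 0 weighting the replica edges
#'   (default 1).
#' @param threshold,thresholdMode Bookkeeping: the threshold the layers were
#'   binarized at.
#' @return A \linkS4class{MultiplexNetwork}.
#' @export
buildSupra <- function(layers, couplingStrength = 1, threshold = NA_real_,
                       thresholdMode = "density") {
  stopifnot(is.list(layers), length(layers) >= 2L)
  if (is.null(names(layers)))
    names(layers) <- paste0("layer", seq_along(layers))
  ns <- vapply(layers, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("layers differ in size: ", paste(ns, collapse = ", "))
  n <- ns[[1L]]
  M <- length(layers)
  supra <- matrix(0, M * n, M * n)
  C <- diag(couplingStrength, n)
  for (a in seq_len(M)) {
    ia <- (a - 1L) * n + seq_len(n)
    supra[ia, ia] <- layers[[a]]
    for (b in seq_len(M)) if (b != a)
      supra[ia, (b - 1L) * n + seq_len(n)] <- C
  }
  nodeNames <- rownames(layers[[1L]])
  if (!is.null(nodeNames)) {
    sn <- as.vector(vapply(names(layers), function(l)
      paste(l, nodeNames, sep = "."), character(n)))
    dimnames(supra) <- list(sn, sn)
  }
  new("MultiplexNetwork", layers = layers,
      couplingStrength = couplingStrength, threshold = threshold,
      thresholdMode = thresholdMode, supra = supra)
}

#' @rdname MultiplexNetwork-class
#' @export
setMethod("layers", "MultiplexNetwork", function(x) x@layers)

#' @rdname MultiplexNetwork-class
#' @export
setMethod("supraAdjacency", "MultiplexNetwork", function(x) x@supra)

setMethod("show", "MultiplexNetwork", function(object) {
  n <- nrow(object@layers[[1L]])
  cat("MultiplexNetwork: ", length(object@layers), " layers (",
      paste(names(object@layers), collapse = ", "), "), ", n,
      " nodes; threshold ", object@threshold, " (", object@thresholdMode,
      "), coupling ", object@couplingStrength, "\n", sep = "")
  dens <- vapply(object@layers, function(A) sum(A) / (n * (n - 1)), 0)
  cat("  layer densities:", paste(sprintf("%.3f", dens), collapse = ", "),
      "\n")
})
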