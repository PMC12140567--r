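# Nodal MPC from an n x M degree matrix; nodes with overlapping degree 0 get
# p = 0 (the formula is 0/0 there; an isolated node participates in no layer).
.mpcFromDegrees <- function(K) {
  M <- ncol(K)
  o <- rowSums(K)
  p <- numeric(nrow(K))
  pos <- o > 0
  if (any(pos))
    p[pos] <- (M / (M - 1)) * (1 - rowSums((K[pos, , drop = FALSE] /
                                            o[pos])^2))
  p
}

#' Intralayer degrees of a multiplex network
#'
#' The degree of node i in layer \eqn{\alpha} is the row sum of that layer's
#' binary adjacency, \eqn{k_i^\alpha = \sum_j a_{ij}^\alpha}. Replica
#' coupling edges are structural and never counted.
#'
#' @param net A \linkS4class{MultiplexNetwork}.
#' @return Integer n x M matrix, one column per layer.
#' @export
intralayerDegrees <- function(net) {
  stopifnot(is(net, "MultiplexNetwork"))
  K <- vapply(layers(net), rowSums, numeric(nrow(layers(net)[[1L]])))
  if (is.null(dim(K))) K <- matrix(K, nrow = 1L,
                                   dimnames = list(NULL, names(layers(net))))
  K
}

#' Overlapping degree
#'
#' The overlapping degree of node i sums its degree over all layers,
#' \eqn{o_i = \sum_\alpha k_i^\alpha}; the global value is the mean of
#' \eqn{o_i} over all nodes (isolated nodes included).
#'
#' @param net A \linkS4class{MultiplexNetwork}.
#' @return List with \code{nodal} (vector \eqn{o_i}) and \code{global}
#'   (scalar mean).
#' @export
overlappingDegree <- function(net) {
  o <- rowSums(intralayerDegrees(net))
  list(nodal = o, global = mean(o))
}

#' Nodal multiplex participation coefficient
#'
#' Measures how uniformly a node's edges are spread across the layers:
#' \deqn{p_i = \frac{M}{M-1}\left(1 - \sum_{\alpha=1}^{M}
#'       \left(\frac{k_i^\alpha}{o_i}\right)^2\right)}
#' so \eqn{p_i = 1} when the node has equal degree in every layer and
#' \eqn{p_i = 0} when all its edges sit in a single layer. Nodes with
#' \eqn{o_i = 0} are assigned \eqn{p_i = 0}, which biases the global mean
#' downward at sparse densities (documented choice; the raw formula is 0/0).
#'
#' @param net A \linkS4class{MultiplexNetwork}.
#' @return Numeric vector \eqn{p_i} in [0, 1], named by region when layers
#'   carry dimnames.
#' @export
nodalMPC <- function(net) {
  K <- intralayerDegrees(net)
  p <- .mpcFromDegrees(K)
  names(p) <- rownames(layers(net)[[1L]])
  p
}

#' Global multiplex participation coefficient
#'
#' Arithmetic mean of the nodal MPC over all nodes, isolated nodes included
#' at value 0 (keeps the node count constant across thresholds and groups).
#'
#' @param net A \linkS4class{MultiplexNetwork}.
#' @return Scalar in [0, 1].
#' @export
globalMPC <- function(net) mean(nodalMPC(net))

#' All multiplex measures at once
#'
#' @param net A \linkS4class{MultiplexNetwork}.
#' @return List with \code{nodal} (data.frame: region, one degree column
#'   \code{k_<layer>} per layer, overlapping degree \code{o}, MPC \code{p}),
#'   \code{global_mpc}, \code{global_overlapping_degree}, \code{threshold},
#'   and \code{n_layers}.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' net <- buildSupra(list(CTH = A, FDG = A), threshold = 0.5)
#' multiplexMeasures(net)$global_mpc  # identical layers: 1
#' @export
multiplexMeasures <- function(net) {
  stopifnot(is(net, "MultiplexNetwork"))
  K <- intralayerDegrees(net)
  o <- rowSums(K)
  p <- .mpcFromDegrees(K)
  region <- rownames(layers(net)[[1L]])
  if (is.null(region)) region <- paste0("node", seq_along(o))
  nodal <- data.frame(region = region, K, o = o, p = p, row.names = NULL,
                      check.names = FALSE)
  colnames(nodal)[1L + seq_len(ncol(K))] <- paste0("k_", names(layers(net)))
  list(nodal = nodal,
       global_mpc = mean(p),
       global_overlapping_degree = mean(o),
       threshold = net@threshold,
       n_layers = length(layers(net)))
}
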