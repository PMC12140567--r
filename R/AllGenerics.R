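#' @rdname RoiAtlas-class
#' @param x A \linkS4class{RoiAtlas} or an object carrying one.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname RoiAtlas-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname RoiAtlas-class
#' @export
setGeneric("atlasName", function(x) standardGeneric("atlasName"))

#' @rdname RoiAtlas-class
#' @export
setGeneric("lobes", function(x) standardGeneric("lobes"))

#' @rdname CohortTable-class
#' @param x A \linkS4class{CohortTable}.
#' @export
setGeneric("atlas", function(x) standardGeneric("atlas"))

#' @rdname CohortTable-class
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))

#' @rdname CohortTable-class
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname LayerMatrix-class
#' @param x A \linkS4class{LayerMatrix}.
#' @export
setGeneric("layerWeights", function(x) standardGeneric("layerWeights"))

#' @rdname MultiplexNetwork-class
#' @param x A \linkS4class{MultiplexNetwork}.
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname MultiplexNetwork-class
#' @export
setGeneric("supraAdjacency", function(x) standardGeneric("supraAdjacency"))
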