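#' Construct an ROI atlas
#'
#' @param name Single text label.
#' @param regions Character vector of unique region identifiers, in the
#'   canonical order all derived matrices will use.
#' @param lobe Optional parallel character vector of lobe tags; defaults to
#'   \code{NA}.
#' @return A \linkS4class{RoiAtlas}.
#' @examples
#' a <- roiAtlas("toy", c("lh-a", "lh-b", "rh-a", "rh-b"))
#' nRegions(a)
#' @export
roiAtlas <- function(name, regions, lobe = rep(NA_character_, length(regions))) {
  new("RoiAtlas", name = as.character(name),
      regions = as.character(regions), lobe = as.character(lobe))
}

.readAtlasFile <- function(file, name) {
  tab <- utils::read.delim(system.file("extdata", file, package = "multiplexSCN",
                                       mustWork = TRUE),
                           stringsAsFactors = FALSE)
  roiAtlas(name, tab$region, tab$lobe)
}

#' Bundled cortical atlases
#'
#' \code{dkAtlas()} returns the 68-region Desikan-Killiany parcellation
#' (34 gyral regions per hemisphere, \code{lh-}/\code{rh-} prefixed) and
#' \code{destrieuxAtlas()} the 148-region Destrieux parcellation (74 per
#' hemisphere). Both carry a coarse lobe tag per region. Atlas size is
#' otherwise a free parameter: any \code{\link{roiAtlas}} works downstream.
#'
#' @return A \linkS4class{RoiAtlas}.
#' @examples
#' nRegions(dkAtlas())
#' head(regions(destrieuxAtlas()))
#' @export
dkAtlas <- function() .readAtlasFile("atlas_dk68.tsv", "DK68")

#' @rdname dkAtlas
#' @export
destrieuxAtlas <- function() .readAtlasFile("atlas_destrieux148.tsv", "Destrieux148")

#' @rdname RoiAtlas-class
#' @aliases regions nRegions atlasName lobes
#' @export
setMethod("regions", "RoiAtlas", function(x) x@regions)

#' @rdname RoiAtlas-class
#' @export
setMethod("nRegions", "RoiAtlas", function(x) length(x@regions))

#' @rdname RoiAtlas-class
#' @export
setMethod("atlasName", "RoiAtlas", function(x) x@name)

#' @rdname RoiAtlas-class
#' @export
setMethod("lobes", "RoiAtlas", function(x) stats::setNames(x@lobe, x@regions))

setMethod("show", "RoiAtlas", function(object) {
  cat("RoiAtlas '", object@name, "': ", length(object@regions),
      " regions\n", sep = "")
  cat("  first:", paste(utils::head(object@regions, 3), collapse = ", "), "...\n")
})
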