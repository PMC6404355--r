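#' Accessors for hepaZone S4 objects
#'
#' Small accessor generics in the Bioconductor style; user code should use
#' these rather than reaching into slots.
#'
#' @param object an S4 object from this package.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("concentrations",
           function(object) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("profileTime", function(object) standardGeneric("profileTime"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("ic50CI", function(object) standardGeneric("ic50CI"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("viability", function(object) standardGeneric("viability"))

#' @rdname accessors
#' @export
setGeneric("sections", function(object) standardGeneric("sections"))

#' @rdname accessors
#' @export
setGeneric("channelMask", function(object) standardGeneric("channelMask"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("dyeName", function(object) standardGeneric("dyeName"))
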