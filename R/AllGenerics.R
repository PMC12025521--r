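#' @include RcppExports.R
NULL

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @export
setGeneric("descriptor", function(x) standardGeneric("descriptor"))

#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @export
setGeneric("plane", function(x) standardGeneric("plane"))

#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))

#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' @export
setGeneric("interfaceRow", function(x) standardGeneric("interfaceRow"))

#' @export
setGeneric("contour", function(x) standardGeneric("contour"))

#' @export
setGeneric("detectionFlag", function(x) standardGeneric("detectionFlag"))

#' @export
setGeneric("measurementValues", function(x) standardGeneric("measurementValues"))

#' @export
setGeneric("textureValues", function(x) standardGeneric("textureValues"))

#' @export
setGeneric("measurementUnits", function(x) standardGeneric("measurementUnits"))

#' @export
setGeneric("templatesFor", function(x, descriptor) standardGeneric("templatesFor"))
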