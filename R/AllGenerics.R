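#' @rdname MaskPattern-class
#' @export
setGeneric("mirrorStates", function(x) standardGeneric("mirrorStates"))

#' @rdname MaskPattern-class
#' @export
setGeneric("onFraction", function(x) standardGeneric("onFraction"))

#' @rdname IntensityMap-class
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname IntensityMap-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname IntensityMap-class
#' @export
setGeneric("physicalExtent", function(x) standardGeneric("physicalExtent"))

#' @rdname SynthesisSchedule-class
#' @export
setGeneric("cycleTable", function(x) standardGeneric("cycleTable"))

#' @rdname SynthesisSchedule-class
#' @export
setGeneric("cycleMasks", function(x) standardGeneric("cycleMasks"))

#' @rdname ProductSet-class
#' @export
setGeneric("products", function(x) standardGeneric("products"))

#' @rdname ProductSet-class
#' @export
setGeneric("designIds", function(x) standardGeneric("designIds"))

#' @rdname ErrorStats-class
#' @export
setGeneric("errorRates", function(x) standardGeneric("errorRates"))

#' @rdname ErrorStats-class
#' @export
setGeneric("perfectMatchFraction",
           function(x) standardGeneric("perfectMatchFraction"))
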