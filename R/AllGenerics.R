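#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the image, mask, trace and curve
#' classes. Bioconductor-style accessors are provided instead of direct
#' slot access.
#'
#' @param x an object.
#' @param object an object.
#' @return The slot value; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @rdname accessors
#' @export
setGeneric("tracePath", function(x) standardGeneric("tracePath"))

#' @rdname accessors
#' @export
setGeneric("traceLength", function(x) standardGeneric("traceLength"))

#' @rdname accessors
#' @export
setGeneric("bodyMask", function(x) standardGeneric("bodyMask"))

#' @rdname accessors
#' @export
setGeneric("combinedMask", function(x) standardGeneric("combinedMask"))

#' @rdname accessors
#' @export
setGeneric("tipPixels", function(x) standardGeneric("tipPixels"))

#' @rdname accessors
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @rdname accessors
#' @export
setGeneric("corrValues", function(x) standardGeneric("corrValues"))
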