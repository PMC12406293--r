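#' @title Accessor generics
#' @description Accessors for the cineRT data classes. Use these rather than
#'   direct slot access.
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("dtMs", function(x) standardGeneric("dtMs"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))

#' @rdname accessors
#' @param slice slice position index.
#' @export
setGeneric("sliceData", function(x, slice) standardGeneric("sliceData"))

#' @rdname accessors
#' @export
setGeneric("edFrames", function(x, ...) standardGeneric("edFrames"))

#' @rdname accessors
#' @export
setGeneric("esFrames", function(x, ...) standardGeneric("esFrames"))

#' @rdname accessors
#' @export
setGeneric("trueMass", function(x) standardGeneric("trueMass"))

#' @rdname accessors
#' @export
setGeneric("respValues", function(x) standardGeneric("respValues"))

#' @rdname accessors
#' @export
setGeneric("respPeaks", function(x) standardGeneric("respPeaks"))

#' @rdname accessors
#' @export
setGeneric("respAmplitude", function(x) standardGeneric("respAmplitude"))

#' @rdname accessors
#' @export
setGeneric("isOriented", function(x) standardGeneric("isOriented"))

#' @rdname accessors
#' @export
setGeneric("gatedFrames", function(x) standardGeneric("gatedFrames"))

#' @rdname accessors
#' @export
setGeneric("gatedPeak", function(x) standardGeneric("gatedPeak"))

#' @rdname accessors
#' @export
setGeneric("areaValues", function(x) standardGeneric("areaValues"))

#' @rdname accessors
#' @export
setGeneric("seriesFrames", function(x) standardGeneric("seriesFrames"))

#' @rdname accessors
#' @export
setGeneric("esOffset", function(x) standardGeneric("esOffset"))

#' @rdname accessors
#' @export
setGeneric("sourceFrames", function(x) standardGeneric("sourceFrames"))

#' @rdname accessors
#' @export
setGeneric("cineData", function(x) standardGeneric("cineData"))

#' @rdname accessors
#' @export
setGeneric("nSys", function(x) standardGeneric("nSys"))

#' @rdname accessors
#' @export
setGeneric("nDia", function(x) standardGeneric("nDia"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
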