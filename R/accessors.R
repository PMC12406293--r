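#' @describeIn accessors number of slice positions in a stack.
#' @export
setMethod("nSlices", "RealTimeStack", function(x) length(x@slices))

#' @describeIn accessors per-slice frame counts (all slices, or one).
#' @export
setMethod("nFrames", "RealTimeStack", function(x, slice = NULL) {
  n <- vapply(x@slices, function(s) dim(s)[3], integer(1))
  if (is.null(slice)) n else n[slice]
})

#' @describeIn accessors temporal resolution (ms).
#' @export
setMethod("dtMs", "RealTimeStack", function(x) x@dtMs)

#' @describeIn accessors in-plane pixel spacing c(row_mm, col_mm).
#' @export
setMethod("pixelSpacing", "RealTimeStack", function(x) x@pixelMm)

#' @describeIn accessors slice thickness (mm).
#' @export
setMethod("sliceThickness", "RealTimeStack", function(x) x@sliceThicknessMm)

#' @describeIn accessors the rows x cols x frames array of one slice.
#' @export
setMethod("sliceData", "RealTimeStack", function(x, slice) {
  stopifnot(slice >= 1L, slice <= length(x@slices))
  x@slices[[slice]]
})

#' @describeIn accessors labelled ED frames of a phantom (one slice or all).
#' @export
setMethod("edFrames", "PhantomTruth", function(x, slice = NULL) {
  if (is.null(slice)) x@edFrames else x@edFrames[[slice]]
})

#' @describeIn accessors labelled ES frames of a phantom (one slice or all).
#' @export
setMethod("esFrames", "PhantomTruth", function(x, slice = NULL) {
  if (is.null(slice)) x@esFrames else x@esFrames[[slice]]
})

#' @describeIn accessors analytic myocardial mass (g) of a phantom.
#' @export
setMethod("trueMass", "PhantomTruth", function(x) x@trueMassG)

#' @describeIn accessors surrogate values, one per timeframe.
#' @export
setMethod("respValues", "RespiratorySignal", function(x) x@values)

#' @describeIn accessors detected end-expiratory peak indices.
#' @export
setMethod("respPeaks", "RespiratorySignal", function(x) x@peaks)

#' @describeIn accessors max minus min of the surrogate.
#' @export
setMethod("respAmplitude", "RespiratorySignal", function(x)
  max(x@values) - min(x@values))

#' @describeIn accessors whether peaks mean end-expiration.
#' @export
setMethod("isOriented", "RespiratorySignal", function(x) x@oriented)

#' @describeIn accessors frames of the respiratory-gated run.
#' @export
setMethod("gatedFrames", "GatedSelection", function(x) x@frames)

#' @describeIn accessors the selected end-expiratory peak index.
#' @export
setMethod("gatedPeak", "GatedSelection", function(x) x@peak)

#' @describeIn accessors LV areas (mm^2), one per frame.
#' @export
setMethod("areaValues", "LvAreaSeries", function(x) x@areaMm2)

#' @describeIn accessors frame indices an area series refers to.
#' @export
setMethod("seriesFrames", "LvAreaSeries", function(x) x@frames)

#' @describeIn accessors position of ES within a slice cine.
#' @export
setMethod("esOffset", "SliceCine", function(x) x@esOffset)

#' @describeIn accessors source-series frame indices of a slice cine.
#' @export
setMethod("sourceFrames", "SliceCine", function(x) x@sourceFrames)

#' @describeIn accessors the rows x cols x slices x time array.
#' @export
setMethod("cineData", "SynchronizedCine", function(x) x@data)

#' @describeIn accessors synchronized systolic frame count.
#' @export
setMethod("nSys", "SynchronizedCine", function(x) x@nSys)

#' @describeIn accessors synchronized diastolic frame count.
#' @export
setMethod("nDia", "SynchronizedCine", function(x) x@nDia)

#' @describeIn accessors number of slices in a synchronized cine.
#' @export
setMethod("nSlices", "SynchronizedCine", function(x) dim(x@data)[3])

#' @describeIn accessors frame-level source mapping of a synchronized cine.
#' @export
setMethod("provenance", "SynchronizedCine", function(x) x@provenance)

#' @describeIn accessors pixel spacing of a synchronized cine.
#' @export
setMethod("pixelSpacing", "SynchronizedCine", function(x) x@pixelMm)

#' @describeIn accessors slice thickness of a synchronized cine.
#' @export
setMethod("sliceThickness", "SynchronizedCine", function(x) x@sliceThicknessMm)

setMethod("show", "RealTimeStack", function(object) {
  nf <- vapply(object@slices, function(s) dim(s)[3], integer(1))
  d <- dim(object@slices[[1]])
  cat("RealTimeStack:", length(object@slices), "slices (apex to base),",
      d[1], "x", d[2], "pixels\n")
  cat("  frames/slice:", paste(range(nf), collapse = "-"),
      " dt:", object@dtMs, "ms\n")
  cat("  spacing:", paste(object@pixelMm, collapse = " x "), "mm, thickness:",
      object@sliceThicknessMm, "mm\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", length(object@edFrames), "slices,",
      "true mass", round(object@trueMassG, 2), "g\n")
  cat("  ED/slice:", paste(range(lengths(object@edFrames)), collapse = "-"),
      " ES/slice:", paste(range(lengths(object@esFrames)), collapse = "-"), "\n")
})

setMethod("show", "RespiratorySignal", function(object) {
  cat("RespiratorySignal:", length(object@values), "timeframes,",
      if (object@oriented) "oriented (peaks = end-expiration)," else "unoriented,",
      length(object@peaks), "peaks\n")
})

setMethod("show", "GatedSelection", function(object) {
  cat("GatedSelection: peak at frame", object@peak, "with",
      length(object@frames), "consecutive frames [",
      min(object@frames), "..", max(object@frames), "]\n")
})

setMethod("show", "LvAreaSeries", function(object) {
  cat("LvAreaSeries:", length(object@frames), "frames [",
      min(object@frames), "..", max(object@frames), "], area",
      round(min(object@areaMm2), 1), "-", round(max(object@areaMm2), 1), "mm^2\n")
})

setMethod("show", "RRInterval", function(object) {
  cat("RRInterval: ED", object@edStart, "-> ES", object@es,
      "-> ED", object@edEnd,
      sprintf(" (%d systolic, %d diastolic frames)\n",
              object@es - object@edStart + 1L, object@edEnd - object@es + 1L))
})

setMethod("show", "SliceCine", function(object) {
  d <- dim(object@frames)
  cat("SliceCine: slice", object@slice, ",", d[3], "frames (ED..ED), ES at",
      object@esOffset, "\n")
})

setMethod("show", "SynchronizedCine", function(object) {
  d <- dim(object@data)
  cat("SynchronizedCine:", d[3], "slices x", d[4], "timeframes (",
      object@nSys, "systolic +", object@nDia, "diastolic, shared ES )\n")
  cat("  ED at index 1 and", d[4], "; ES at index", object@nSys, "\n")
})
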