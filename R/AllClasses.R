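#' @import methods
NULL

#' RealTimeStack: a multi-slice real-time acquisition
#'
#' Container for a short-axis real-time CMR study: one 2D image time series
#' per slice position, ordered apex to base, with the geometry needed for
#' volumetry. Slices are imaged sequentially, so neither cardiac nor
#' respiratory phase is aligned across slices.
#'
#' @slot slices list of 3D numeric arrays (rows x cols x frames), apex first.
#'   Frame counts may differ between slices; in-plane dimensions may not.
#' @slot dtMs reconstructed temporal resolution in milliseconds.
#' @slot pixelMm in-plane pixel spacing, c(row_mm, col_mm).
#' @slot sliceThicknessMm slice thickness in millimetres.
#'
#' @seealso [generatePhantom()], [loadStack()], [writeStack()]
#' @export
setClass("RealTimeStack",
  representation(
    slices = "list",
    dtMs = "numeric",
    pixelMm = "numeric",
    sliceThicknessMm = "numeric"
  )
)

setValidity("RealTimeStack", function(object) {
  msg <- character()
  if (length(object@slices) < 1L)
    msg <- c(msg, "stack must contain at least one slice")
  dims <- lapply(object@slices, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each slice must be a rows x cols x frames array")
  if (length(msg) == 0L) {
    inplane <- vapply(dims, function(d) d[1:2], numeric(2))
    if (any(inplane[1, ] != inplane[1, 1]) || any(inplane[2, ] != inplane[2, 1])) {
      bad <- which(inplane[1, ] != inplane[1, 1] | inplane[2, ] != inplane[2, 1])
      msg <- c(msg, paste0("inconsistent in-plane dimensions in slices: ",
                           paste(bad, collapse = ", ")))
    }
  }
  if (length(object@dtMs) != 1L || !is.finite(object@dtMs) || object@dtMs <= 0)
    msg <- c(msg, "dtMs must be a single positive number")
  if (length(object@pixelMm) != 2L || any(object@pixelMm <= 0))
    msg <- c(msg, "pixelMm must be two positive spacings (row, col)")
  if (length(object@sliceThicknessMm) != 1L || object@sliceThicknessMm <= 0)
    msg <- c(msg, "sliceThicknessMm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PhantomParams: configuration of the digital cardiorespiratory phantom
#'
#' All geometric quantities are in millimetres, rates in their stated units.
#' Defaults emulate a patient-like real-time exercise acquisition: 36 ms
#' temporal resolution, 1.9 x 2.8 mm in-plane spacing, 14 slices, 250
#' timeframes per slice, exercise-range heart rate.
#'
#' @slot nSlices number of slice positions (apex to base).
#' @slot nFrames timeframes per slice.
#' @slot dtMs temporal resolution (ms).
#' @slot pixelMm in-plane spacing c(row_mm, col_mm).
#' @slot sliceThicknessMm slice thickness (mm).
#' @slot grid image size c(rows, cols).
#' @slot heartRateBpm mean heart rate (beats/min).
#' @slot hrJitterFrac fractional beat-to-beat period jitter (uniform).
#' @slot systoleFrac fraction of the cardiac period from ED to ES.
#' @slot respRateBpm respiratory rate (breaths/min).
#' @slot respAmpPx peak-to-peak in-plane respiratory translation (pixels,
#'   row direction).
#' @slot rEndoEdMm,rEndoEsMm base-level endocardial radius at ED and ES.
#' @slot ringAreaMm2 myocardial annulus cross-section area, held constant
#'   over the cycle (incompressible myocardium).
#' @slot noiseSd additive Gaussian noise SD relative to myocardial intensity.
#' @slot seed RNG seed.
#' @export
setClass("PhantomParams",
  representation(
    nSlices = "integer", nFrames = "integer", dtMs = "numeric",
    pixelMm = "numeric", sliceThicknessMm = "numeric", grid = "integer",
    heartRateBpm = "numeric", hrJitterFrac = "numeric", systoleFrac = "numeric",
    respRateBpm = "numeric", respAmpPx = "numeric",
    rEndoEdMm = "numeric", rEndoEsMm = "numeric", ringAreaMm2 = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@dtMs <= 0) msg <- c(msg, "dtMs must be positive")
  if (length(object@pixelMm) != 2L || any(object@pixelMm <= 0))
    msg <- c(msg, "pixelMm must be two positive spacings")
  if (object@sliceThicknessMm <= 0) msg <- c(msg, "sliceThicknessMm must be positive")
  if (length(object@grid) != 2L || any(object@grid < 8L))
    msg <- c(msg, "grid must be c(rows, cols), each >= 8")
  if (object@heartRateBpm <= 0) msg <- c(msg, "heartRateBpm must be positive")
  if (object@hrJitterFrac < 0 || object@hrJitterFrac >= 1)
    msg <- c(msg, "hrJitterFrac must be in [0, 1)")
  if (object@systoleFrac <= 0 || object@systoleFrac >= 1)
    msg <- c(msg, "systoleFrac must be in (0, 1)")
  if (object@respRateBpm <= 0) msg <- c(msg, "respRateBpm must be positive")
  if (object@respAmpPx < 0) msg <- c(msg, "respAmpPx must be >= 0")
  if (object@rEndoEsMm >= object@rEndoEdMm)
    msg <- c(msg, "rEndoEsMm must be strictly smaller than rEndoEdMm")
  if (object@rEndoEsMm <= 0) msg <- c(msg, "endocardial radii must be positive")
  if (object@ringAreaMm2 <= 0) msg <- c(msg, "ringAreaMm2 must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth accompanying a generated phantom
#'
#' Per-slice, per-frame ground truth used as the oracle for every pipeline
#' stage: true respiratory displacement, cardiac phase (0 = ED), labelled
#' ED/ES frames, rasterized endo-/epicardial masks, and the analytic
#' myocardial mass.
#'
#' @slot respDisplacement list (per slice) of per-frame in-plane translation
#'   in pixels (row direction, 0 = end-expiration).
#' @slot cardiacPhase list (per slice) of per-frame phase in [0, 1), 0 = ED.
#' @slot edFrames,esFrames list (per slice) of labelled frame indices.
#' @slot endoMasks,epiMasks list (per slice) of rows x cols x frames logical
#'   arrays.
#' @slot trueMassG analytic myocardial mass in grams.
#' @slot params the [PhantomParams-class] that produced the phantom.
#' @export
setClass("PhantomTruth",
  representation(
    respDisplacement = "list", cardiacPhase = "list",
    edFrames = "list", esFrames = "list",
    endoMasks = "list", epiMasks = "list",
    trueMassG = "numeric", params = "PhantomParams"
  )
)

#' RespiratorySignal: 1D respiratory surrogate for one slice series
#'
#' One scalar per timeframe obtained from the spectral embedding of the
#' diaphragm ROI. Until oriented, the sign is arbitrary (eigenvectors are
#' defined up to sign); after [orientForExpiration()] peaks correspond to
#' end-expiration.
#'
#' @slot values one coordinate per timeframe, scaled to unit SD.
#' @slot oriented logical; TRUE once peaks mean end-expiration.
#' @slot peaks ascending indices of detected end-expiratory peaks (filled by
#'   peak detection; empty beforehand).
#' @slot dtMs temporal resolution of the series (ms); NA if unknown.
#' @export
setClass("RespiratorySignal",
  representation(
    values = "numeric", oriented = "logical",
    peaks = "integer", dtMs = "numeric"
  )
)

setValidity("RespiratorySignal", function(object) {
  msg <- character()
  if (length(object@oriented) != 1L) msg <- c(msg, "oriented must be a single flag")
  if (is.unsorted(object@peaks, strictly = TRUE) && length(object@peaks) > 1L)
    msg <- c(msg, "peaks must be strictly ascending")
  if (length(object@peaks) &&
      (min(object@peaks) < 1L || max(object@peaks) > length(object@values)))
    msg <- c(msg, "peaks out of range")
  if (length(msg)) msg else TRUE
})

#' GatedSelection: consecutive timeframes near one end-expiratory peak
#'
#' The respiratory-gated set: the maximal run of consecutive timeframes
#' containing the chosen peak whose signal stays within the tolerance band
#' below the peak value.
#'
#' @slot peak index of the selected end-expiratory peak.
#' @slot frames consecutive frame indices of the selected run (ascending,
#'   gap-free, containing the peak).
#' @slot values the signal values at those frames.
#' @export
setClass("GatedSelection",
  representation(peak = "integer", frames = "integer", values = "numeric")
)

setValidity("GatedSelection", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@values))
    msg <- c(msg, "frames and values lengths differ")
  if (length(object@frames) &&
      any(diff(object@frames) != 1L))
    msg <- c(msg, "frames must be consecutive")
  if (length(object@frames) && !(object@peak %in% object@frames))
    msg <- c(msg, "frames must contain the peak")
  if (length(msg)) msg else TRUE
})

#' LvAreaSeries: cross-sectional LV area per timeframe
#'
#' @slot frames the (consecutive) frame indices the areas belong to, in the
#'   coordinates of the original slice series.
#' @slot areaMm2 one non-negative area per frame.
#' @slot pixelAreaMm2 area of one pixel.
#' @export
setClass("LvAreaSeries",
  representation(frames = "integer", areaMm2 = "numeric", pixelAreaMm2 = "numeric")
)

setValidity("LvAreaSeries", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@areaMm2))
    msg <- c(msg, "frames and areaMm2 lengths differ")
  if (any(object@areaMm2 < 0)) msg <- c(msg, "areas must be >= 0")
  if (length(object@frames) > 1L && any(diff(object@frames) != 1L))
    msg <- c(msg, "frames must be consecutive")
  if (length(msg)) msg else TRUE
})

#' RRInterval: one cardiac cycle bounded by two consecutive ED frames
#'
#' @slot edStart,es,edEnd frame indices (in the slice series) of the opening
#'   ED, the enclosed ES, and the closing ED. Both limbs must contain at
#'   least two frames.
#' @export
setClass("RRInterval",
  representation(edStart = "integer", es = "integer", edEnd = "integer")
)

setValidity("RRInterval", function(object) {
  msg <- character()
  if (!(object@edStart < object@es && object@es < object@edEnd))
    msg <- c(msg, "need edStart < es < edEnd")
  else {
    if (object@es - object@edStart + 1L < 2L)
      msg <- c(msg, "systolic limb must have >= 2 frames")
    if (object@edEnd - object@es + 1L < 2L)
      msg <- c(msg, "diastolic limb must have >= 2 frames")
  }
  if (length(msg)) msg else TRUE
})

#' SliceCine: one R-R interval of one slice, ED to ED inclusive
#'
#' @slot slice slice position index (apex = 1).
#' @slot frames rows x cols x time array covering the interval; the first and
#'   last frames are the bounding EDs.
#' @slot esOffset index of ES within `frames` (1 < esOffset < time length).
#' @slot sourceFrames indices of `frames` in the original slice series.
#' @slot dtMs,pixelMm,sliceThicknessMm geometry carried from the stack.
#' @export
setClass("SliceCine",
  representation(
    slice = "integer", frames = "array", esOffset = "integer",
    sourceFrames = "integer", dtMs = "numeric", pixelMm = "numeric",
    sliceThicknessMm = "numeric"
  )
)

setValidity("SliceCine", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be rows x cols x time")
  else {
    len <- d[3]
    if (!(object@esOffset > 1L && object@esOffset < len))
      msg <- c(msg, "esOffset must lie strictly inside the interval")
    if (length(object@sourceFrames) != len)
      msg <- c(msg, "sourceFrames length must equal the time dimension")
  }
  if (length(msg)) msg else TRUE
})

#' SynchronizedCine: slices x time cine with ED and ES aligned
#'
#' Every slice has its bounding EDs at time indices 1 and nSys + nDia - 1 and
#' its ES at index nSys; the ES frame is shared between the systolic and
#' diastolic limbs, so the time length is nSys + nDia - 1. The trailing ED
#' duplicate is kept so the interval bounds are unambiguous; drop it for
#' cyclic playback.
#'
#' @slot data rows x cols x slices x time array, slice order apex to base.
#' @slot nSys,nDia across-slice minimum systolic and diastolic frame counts.
#' @slot pixelMm,sliceThicknessMm geometry.
#' @slot provenance data.frame mapping every output frame to its source:
#'   columns slice, timeIndex, sampleTime (position within the source R-R
#'   interval, in source-frame units), srcLo, srcHi, weight (interpolation
#'   weight on srcHi), srcGlobalLo, srcGlobalHi (indices in the original
#'   slice series).
#' @export
setClass("SynchronizedCine",
  representation(
    data = "array", nSys = "integer", nDia = "integer",
    pixelMm = "numeric", sliceThicknessMm = "numeric",
    provenance = "data.frame"
  )
)

setValidity("SynchronizedCine", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be rows x cols x slices x time")
  else if (d[4] != object@nSys + object@nDia - 1L)
    msg <- c(msg, "time length must equal nSys + nDia - 1")
  if (length(msg)) msg else TRUE
})
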