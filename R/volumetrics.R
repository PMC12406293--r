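#' LV cavity volume by slice summation
#'
#' Simpson slice summation: the sum over slices of mask area times slice
#' thickness, converted to millilitres.
#'
#' @param endoMasks list with one binary rows x cols mask per slice (use NULL
#'   entries to flag missing slices, which is an error).
#' @param pixelAreaMm2 area of one pixel (mm^2).
#' @param sliceThicknessMm slice thickness (mm).
#' @return volume in mL.
#' @export
lvVolume <- function(endoMasks, pixelAreaMm2, sliceThicknessMm) {
  stopifnot(is.list(endoMasks), pixelAreaMm2 > 0, sliceThicknessMm > 0)
  missing <- which(vapply(endoMasks, is.null, logical(1)))
  if (length(missing))
    stop("missing mask for slice(s): ", paste(missing, collapse = ", "))
  counts <- vapply(endoMasks, function(m) sum(m != 0), numeric(1))
  sum(counts) * pixelAreaMm2 * sliceThicknessMm / 1000
}

#' LV myocardial mass by slice summation
#'
#' Mass is (epicardial volume - endocardial volume) times myocardial
#' density. The endocardium must lie inside the epicardium; pixels outside
#' are clipped by intersection with a warning, and an excess above 5% of the
#' epicardial area is treated as a delineation inconsistency and rejected.
#'
#' @param epiMasks,endoMasks lists of per-slice binary masks.
#' @param pixelAreaMm2 area of one pixel (mm^2).
#' @param sliceThicknessMm slice thickness (mm).
#' @param densityGPerMl myocardial density; default 1.05 g/mL.
#' @return mass in grams.
#' @export
lvMass <- function(epiMasks, endoMasks, pixelAreaMm2, sliceThicknessMm,
                   densityGPerMl = 1.05) {
  stopifnot(length(epiMasks) == length(endoMasks))
  endoClipped <- vector("list", length(endoMasks))
  clipped <- FALSE
  for (s in seq_along(epiMasks)) {
    epi <- epiMasks[[s]] != 0; endo <- endoMasks[[s]] != 0
    outside <- sum(endo & !epi)
    if (outside > 0.05 * max(sum(epi), 1L))
      stop("slice ", s, ": endocardium exceeds epicardium by ", outside,
           " pixels (> 5% of epicardial area); inconsistent delineations")
    if (outside > 0) clipped <- TRUE
    endoClipped[[s]] <- endo & epi
  }
  if (clipped)
    warning("endocardial pixels outside the epicardium were clipped")
  vEpi <- lvVolume(lapply(epiMasks, function(m) m != 0),
                   pixelAreaMm2, sliceThicknessMm)
  vEndo <- lvVolume(endoClipped, pixelAreaMm2, sliceThicknessMm)
  (vEpi - vEndo) * densityGPerMl
}

#' Resample per-slice mask series onto a synchronized cine's time grid
#'
#' Uses the cine's provenance to apply the same temporal sampling to binary
#' masks as was applied to the images: per-pixel linear interpolation
#' between the bracketing source masks, thresholded at 0.5.
#'
#' @param cine a [SynchronizedCine-class].
#' @param masks list (per slice, apex to base) of rows x cols x frames
#'   logical arrays in the original slice-series frame coordinates.
#' @return logical rows x cols x slices x time array aligned with the cine.
#' @export
alignMasks <- function(cine, masks) {
  stopifnot(is(cine, "SynchronizedCine"))
  d <- dim(cine@data)
  if (length(masks) != d[3])
    stop("need one mask series per slice (", d[3], "), got ", length(masks))
  out <- array(FALSE, d)
  pr <- cine@provenance
  for (r in seq_len(nrow(pr))) {
    s <- pr$slice[r]; t <- pr$timeIndex[r]
    lo <- masks[[s]][, , pr$srcGlobalLo[r]]
    if (pr$weight[r] == 0) out[, , s, t] <- lo != 0
    else {
      hi <- masks[[s]][, , pr$srcGlobalHi[r]]
      out[, , s, t] <-
        (1 - pr$weight[r]) * (lo != 0) + pr$weight[r] * (hi != 0) >= 0.5
    }
  }
  out
}

#' LV volume curve of a synchronized cine
#'
#' @param alignedEndo logical rows x cols x slices x time array from
#'   [alignMasks()].
#' @param pixelAreaMm2,sliceThicknessMm geometry.
#' @return numeric vector of volumes (mL), one per timeframe.
#' @export
volumeCurve <- function(alignedEndo, pixelAreaMm2, sliceThicknessMm) {
  stopifnot(length(dim(alignedEndo)) == 4L)
  d <- dim(alignedEndo)
  vapply(seq_len(d[4]), function(t)
    lvVolume(lapply(seq_len(d[3]), function(s) alignedEndo[, , s, t]),
             pixelAreaMm2, sliceThicknessMm),
    numeric(1))
}

#' Identify the four analysis phases on a synchronized volume curve
#'
#' ED and ES are fixed by the synchronization (time index 1 and nSys). Mid
#' systole (MS) defaults to the midpoint of the systolic limb and early
#' rapid filling (ERF) to the start of the steepest volume upslope at or
#' after ES (the frame of fastest early filling), forced strictly after ES.
#' Both defaults can be overridden with manual picks.
#'
#' @param curve numeric volume curve from a synchronized cine.
#' @param nSys systolic frame count of the cine (ES index).
#' @param msOverride,erfOverride optional manual frame indices.
#' @return list with integer elements `ed`, `ms`, `es`, `erf`.
#' @export
identifyPhases <- function(curve, nSys, msOverride = NULL,
                           erfOverride = NULL) {
  n <- length(curve)
  nSys <- as.integer(nSys)
  stopifnot(nSys >= 2L, nSys < n)
  ed <- 1L
  es <- nSys
  ms <- if (!is.null(msOverride)) as.integer(msOverride)
  else as.integer(round((1 + nSys) / 2))
  if (!is.null(erfOverride)) erf <- as.integer(erfOverride)
  else {
    dv <- diff(curve)                           # dv[j] = curve[j+1] - curve[j]
    cand <- es:(n - 1L)
    if (all(dv[cand] <= 0))
      stop("flat or non-filling diastolic curve: specify erfOverride")
    erf <- cand[which.max(dv[cand])]
    erf <- max(erf, es + 1L)
  }
  if (!(ed < ms && ms < es && es < erf))
    stop("phase ordering violated: need ed < ms < es < erf, got ",
         paste(c(ed, ms, es, erf), collapse = ", "))
  list(ed = ed, ms = ms, es = es, erf = as.integer(erf))
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements, reports the mean difference (bias), the sample
#' SD of the differences, the limits of agreement bias ± 1.96 SD, and
#' optionally the bias and SD as a percentage of a stated reference mean
#' (e.g. the resting LV mass).
#'
#' @param x,y paired numeric vectors; differences are `x - y`.
#' @param referenceMean optional reference for the percentage variants.
#' @return list with `bias`, `sd`, `loa` (length 2), and when a reference is
#'   given, `percentBias` and `percentSd`.
#' @export
blandAltman <- function(x, y, referenceMean = NULL) {
  if (length(x) != length(y))
    stop("x and y must have equal length, got ", length(x), " and ",
         length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdv <- stats::sd(d)
  out <- list(bias = bias, sd = sdv,
              loa = c(bias - 1.96 * sdv, bias + 1.96 * sdv))
  if (!is.null(referenceMean)) {
    out$percentBias <- 100 * bias / referenceMean
    out$percentSd <- 100 * sdv / referenceMean
  }
  out
}
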