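#' Build a SliceCine from a stack slice and an R-R interval
#'
#' Cuts the ED..ED frames of one slice out of the stack and records where
#' they came from.
#'
#' @param stack a [RealTimeStack-class].
#' @param slice slice position index.
#' @param rr an [RRInterval-class] in that slice's frame coordinates.
#' @return a [SliceCine-class].
#' @export
sliceCine <- function(stack, slice, rr) {
  stopifnot(is(stack, "RealTimeStack"), is(rr, "RRInterval"))
  ser <- sliceData(stack, slice)
  if (rr@edEnd > dim(ser)[3])
    stop("R-R interval end ", rr@edEnd, " beyond slice ", slice,
         " frame count ", dim(ser)[3])
  src <- rr@edStart:rr@edEnd
  new("SliceCine", slice = as.integer(slice),
      frames = ser[, , src, drop = FALSE],
      esOffset = rr@es - rr@edStart + 1L,
      sourceFrames = as.integer(src),
      dtMs = stack@dtMs, pixelMm = stack@pixelMm,
      sliceThicknessMm = stack@sliceThicknessMm)
}

#' Split a slice cine into its systolic and diastolic limbs
#'
#' The ES frame belongs to both limbs: systolic frames run ED..ES inclusive,
#' diastolic frames ES..ED inclusive. Concatenating the limbs and dropping
#' one shared ES frame reproduces the input.
#'
#' @param cine a [SliceCine-class].
#' @return list with 3D arrays `systolic` and `diastolic`.
#' @export
splitIntervals <- function(cine) {
  stopifnot(is(cine, "SliceCine"))
  validObject(cine)
  len <- dim(cine@frames)[3]
  es <- cine@esOffset
  list(systolic = cine@frames[, , 1:es, drop = FALSE],
       diastolic = cine@frames[, , es:len, drop = FALSE])
}

# endpoint-inclusive uniform source positions for resampling L frames to n
.samplePositions <- function(L, n) {
  if (n == L) return(as.numeric(1:L))
  pos <- 1 + (seq_len(n) - 1) * (L - 1) / (n - 1)
  pos[1] <- 1; pos[n] <- L
  pos
}

# decompose positions into bracketing indices and interpolation weights,
# snapping near-integer positions so grid points are copied exactly
.sampleWeights <- function(pos, L) {
  lo <- floor(pos)
  w <- pos - lo
  snap <- w < 1e-9
  w[snap] <- 0
  up <- w > 1 - 1e-9
  lo[up] <- lo[up] + 1L
  w[up] <- 0
  hi <- pmin(lo + 1L, L)
  list(lo = as.integer(lo), hi = as.integer(hi), w = w)
}

#' Temporally down-sample an image sequence
#'
#' Per-pixel linear interpolation along the time axis on an
#' endpoint-inclusive uniform grid: output frame j is sampled at source
#' position 1 + (j-1)(L-1)/(n-1). The first and last output frames equal the
#' first and last input frames exactly, and source positions are strictly
#' increasing (no frame reordering). Only down-sampling (or the identity) is
#' supported, matching the synchronization step's contract.
#'
#' @param frames rows x cols x time numeric array (or a plain numeric vector
#'   treated as a single-pixel sequence).
#' @param nTarget number of output frames, 2 <= nTarget <= input length.
#' @return resampled array (or vector) with `nTarget` frames.
#' @export
resampleTime <- function(frames, nTarget) {
  vec <- is.null(dim(frames))
  if (vec) frames <- array(frames, c(1, 1, length(frames)))
  stopifnot(length(dim(frames)) == 3L)
  L <- dim(frames)[3]
  nTarget <- as.integer(nTarget)
  if (nTarget < 2L) stop("nTarget must be >= 2")
  if (L < 2L) stop("input must have >= 2 frames")
  if (nTarget > L)
    stop("nTarget ", nTarget, " exceeds input length ", L,
         ": only temporal down-sampling is supported")
  sw <- .sampleWeights(.samplePositions(L, nTarget), L)
  d <- dim(frames)
  out <- array(0, c(d[1], d[2], nTarget))
  for (j in seq_len(nTarget)) {
    out[, , j] <- if (sw$w[j] == 0) frames[, , sw$lo[j]]
    else (1 - sw$w[j]) * frames[, , sw$lo[j]] + sw$w[j] * frames[, , sw$hi[j]]
  }
  if (vec) as.numeric(out) else out
}

#' Synchronize R-R intervals across slice positions
#'
#' Aligns the ED and ES timeframes of every slice: the systolic and
#' diastolic limbs are resampled independently to the across-slice minimum
#' systolic and diastolic frame counts ([resampleTime()]), then rejoined on
#' the shared ES frame. In the result every slice has ED at time index 1
#' (and the final index) and ES at index nSys.
#'
#' @param sliceCines list of [SliceCine-class], ordered apex to base.
#' @return a [SynchronizedCine-class].
#' @export
synchronize <- function(sliceCines) {
  stopifnot(length(sliceCines) >= 2L,
            all(vapply(sliceCines, is, logical(1), "SliceCine")))
  inplane <- vapply(sliceCines, function(x) dim(x@frames)[1:2], integer(2))
  if (any(inplane[1, ] != inplane[1, 1]) || any(inplane[2, ] != inplane[2, 1]))
    stop("inconsistent in-plane geometry across slice cines")

  sysCounts <- vapply(sliceCines, function(x) x@esOffset, integer(1))
  diaCounts <- vapply(sliceCines, function(x)
    dim(x@frames)[3] - x@esOffset + 1L, integer(1))
  bad <- which(sysCounts < 2L | diaCounts < 2L)
  if (length(bad))
    stop("slice(s) ", paste(bad, collapse = ", "),
         " have a limb with fewer than 2 frames")

  nSys <- min(sysCounts); nDia <- min(diaCounts)
  tLen <- nSys + nDia - 1L
  d <- dim(sliceCines[[1]]@frames)
  nS <- length(sliceCines)
  data <- array(0, c(d[1], d[2], nS, tLen))
  prov <- vector("list", nS)

  for (s in seq_len(nS)) {
    cine <- sliceCines[[s]]
    limbs <- splitIntervals(cine)
    sysPos <- .samplePositions(sysCounts[s], nSys)
    diaPos <- .samplePositions(diaCounts[s], nDia)
    data[, , s, 1:nSys] <- resampleTime(limbs$systolic, nSys)
    data[, , s, nSys:tLen] <- resampleTime(limbs$diastolic, nDia)

    # provenance: positions within the slice's own R-R interval
    posAll <- c(sysPos, cine@esOffset - 1L + diaPos[-1])
    sw <- .sampleWeights(posAll, dim(cine@frames)[3])
    prov[[s]] <- data.frame(
      slice = s, timeIndex = seq_len(tLen), sampleTime = posAll,
      srcLo = sw$lo, srcHi = sw$hi, weight = sw$w,
      srcGlobalLo = cine@sourceFrames[sw$lo],
      srcGlobalHi = cine@sourceFrames[sw$hi])
  }

  new("SynchronizedCine", data = data, nSys = nSys, nDia = nDia,
      pixelMm = sliceCines[[1]]@pixelMm,
      sliceThicknessMm = sliceCines[[1]]@sliceThicknessMm,
      provenance = do.call(rbind, prov))
}

#' Decompose a synchronized cine back into per-slice cines
#'
#' Utility for inspecting or re-synchronizing: each slice of the cine
#' becomes a [SliceCine-class] with ES at nSys. Re-synchronizing the result
#' is the identity (all slices already sit at the minimum counts).
#'
#' @param cine a [SynchronizedCine-class].
#' @param dtMs nominal temporal resolution for the derived cines.
#' @return list of [SliceCine-class].
#' @export
asSliceCines <- function(cine, dtMs = NA_real_) {
  stopifnot(is(cine, "SynchronizedCine"))
  d <- dim(cine@data)
  lapply(seq_len(d[3]), function(s)
    new("SliceCine", slice = as.integer(s),
        frames = cine@data[, , s, , drop = TRUE],
        esOffset = cine@nSys,
        sourceFrames = seq_len(d[4]),
        dtMs = as.numeric(dtMs), pixelMm = cine@pixelMm,
        sliceThicknessMm = cine@sliceThicknessMm))
}
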