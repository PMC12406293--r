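#' Segment the LV blood pool in a set of frames
#'
#' Segmentation is a pluggable contract: any function mapping a
#' rows x cols x frames array to binary masks of the same shape can stand in
#' (the original method used a pretrained CNN; precomputed masks can be
#' passed through unchanged). The bundled reference segmenter is intended
#' for bright-blood phantom-like contrast: it thresholds each frame at the
#' Otsu level, optionally restricts to a circular search region, keeps the
#' largest connected bright component, and fills holes.
#'
#' @param frames rows x cols x frames numeric array.
#' @param segmenter `"reference"`, a function(frames) -> logical array, or
#'   `"masks"` together with `masks`.
#' @param masks precomputed logical array (rows x cols x frames) passed
#'   through unchanged when `segmenter = "masks"`.
#' @param searchCenter,searchRadiusPx optional circular search region
#'   (pixels) for the reference segmenter; default: whole image.
#' @return logical array of masks, same dimensions as `frames`.
#' @export
segmentLV <- function(frames, segmenter = "reference", masks = NULL,
                      searchCenter = NULL, searchRadiusPx = NULL) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 1L)
  if (is.function(segmenter)) {
    out <- segmenter(frames)
  } else if (identical(segmenter, "masks")) {
    stopifnot(!is.null(masks))
    if (!identical(dim(masks), dim(frames)))
      stop("precomputed masks dimensions ",
           paste(dim(masks), collapse = "x"),
           " do not match frames ", paste(dim(frames), collapse = "x"))
    return(masks)                               # identity contract
  } else if (identical(segmenter, "reference")) {
    out <- .referenceSegmenter(frames, searchCenter, searchRadiusPx)
  } else stop("unknown segmenter: ", segmenter)

  emptyFrac <- mean(apply(out, 3, sum) == 0)
  if (emptyFrac > 0.5)
    stop("segmenter '",
         if (is.function(segmenter)) "user-function" else segmenter,
         "' produced empty masks in ", round(100 * emptyFrac),
         "% of frames")
  out
}

# Bright-blood reference segmenter. Per frame: (1) Otsu separates air/lung
# background from tissue; (2) a second Otsu within the tissue intensities
# separates the brightest (blood) class; (3) components touching the image
# border are discarded (subdiaphragmatic tissue extends off-field, the LV
# pool never does), the largest remaining component is kept and its holes
# filled. Only warranted for bSSFP-like contrast (blood brightest).
.referenceSegmenter <- function(frames, searchCenter, searchRadiusPx) {
  d <- dim(frames)
  region <- if (!is.null(searchRadiusPx)) {
    if (is.null(searchCenter)) searchCenter <- (d[1:2] + 1) / 2
    outer(seq_len(d[1]), seq_len(d[2]), function(r, c)
      (r - searchCenter[1])^2 + (c - searchCenter[2])^2) <= searchRadiusPx^2
  } else matrix(TRUE, d[1], d[2])

  out <- array(FALSE, d)
  for (f in seq_len(d[3])) {
    img <- frames[, , f]
    rng <- range(img)
    if (rng[2] <= rng[1]) next                  # flat frame -> empty mask
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    th1 <- EBImage::otsu(EBImage::Image(norm))
    tissue <- norm > th1
    if (!any(tissue)) next
    th2 <- EBImage::otsu(EBImage::Image(matrix(norm[tissue], ncol = 1)))
    bw <- (norm > th2) & region
    if (!any(bw)) next
    lab <- EBImage::bwlabel(bw)
    nlab <- max(lab)
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    keepable <- setdiff(seq_len(nlab), border)
    if (!length(keepable)) next
    sizes <- tabulate(lab[lab > 0], nbins = nlab)
    biggest <- keepable[which.max(sizes[keepable])]
    mask <- EBImage::fillHull(lab == biggest)
    out[, , f] <- as.logical(mask)
  }
  out
}

#' Cross-sectional LV area per frame from binary masks
#'
#' @param masks rows x cols x frames logical (or 0/1) array.
#' @param pixelAreaMm2 area of one pixel (mm^2).
#' @param frames frame indices the masks correspond to (defaults to
#'   1..n, i.e. the masks' own ordering).
#' @return an [LvAreaSeries-class].
#' @export
areaSeries <- function(masks, pixelAreaMm2, frames = NULL) {
  stopifnot(length(dim(masks)) == 3L, pixelAreaMm2 > 0)
  if (is.null(frames)) frames <- seq_len(dim(masks)[3])
  counts <- apply(masks != 0, 3, sum)
  new("LvAreaSeries", frames = as.integer(frames),
      areaMm2 = counts * pixelAreaMm2,
      pixelAreaMm2 = as.numeric(pixelAreaMm2))
}

.seriesValues <- function(series) {
  if (is(series, "LvAreaSeries")) series@areaMm2 else as.numeric(series)
}

.seriesIndex <- function(series) {
  if (is(series, "LvAreaSeries")) series@frames
  else seq_along(as.numeric(series))
}

#' Detect end-diastolic timeframes from an LV area series
#'
#' An ED timeframe has a strictly larger LV area than its `window` nearest
#' frames in each direction (default three). Only frames with a full window
#' on both sides are eligible. Plateaus of equal maxima satisfy the
#' non-strict but not the strict rule; they yield no detection and a
#' warning.
#'
#' @param series an [LvAreaSeries-class] or plain numeric vector.
#' @param window neighbourhood half-width in frames.
#' @return integer ED indices, in the series' frame coordinates. Errors with
#'   a "NoRRInterval" condition if fewer than two EDs are found.
#' @export
detectED <- function(series, window = 3L) {
  v <- .seriesValues(series)
  idx <- .seriesIndex(series)
  n <- length(v)
  window <- as.integer(window)
  if (n <= 2L * window)
    stop("series length ", n, " must exceed 2 * window = ", 2L * window)

  hits <- logical(n)
  plateau <- FALSE
  for (i in (window + 1L):(n - window)) {
    nb <- v[c((i - window):(i - 1L), (i + 1L):(i + window))]
    if (all(v[i] > nb)) hits[i] <- TRUE
    else if (all(v[i] >= nb) && any(v[i] == nb)) plateau <- TRUE
  }
  if (plateau)
    warning("plateau of equal maximal areas found; the strict ED rule ",
            "detects none of its frames")
  ed <- which(hits)
  if (length(ed) < 2L) {
    cond <- simpleError(
      paste0("NoRRInterval: found ", length(ed),
             " ED timeframe(s); two consecutive EDs are needed to bound ",
             "an R-R interval"))
    class(cond) <- c("NoRRInterval", class(cond))
    stop(cond)
  }
  idx[ed]
}

#' Detect end-systolic timeframes between consecutive EDs
#'
#' ES is the timeframe with the smallest LV area strictly between two
#' consecutive ED frames; ties go to the earliest frame.
#'
#' @param series an [LvAreaSeries-class] or plain numeric vector.
#' @param edIndices ED indices as returned by [detectED()] (same frame
#'   coordinates as the series).
#' @return integer ES indices, one per consecutive ED pair.
#' @export
detectES <- function(series, edIndices) {
  v <- .seriesValues(series)
  idx <- .seriesIndex(series)
  if (length(edIndices) < 2L)
    stop("need at least two ED indices")
  pos <- match(edIndices, idx)
  if (anyNA(pos)) stop("ED indices not found in the series frames")
  vapply(seq_len(length(pos) - 1L), function(k) {
    a <- pos[k]; b <- pos[k + 1L]
    if (b - a < 2L) stop("ED frames ", idx[a], " and ", idx[b],
                         " have no frame between them")
    inner <- (a + 1L):(b - 1L)
    idx[inner[which.min(v[inner])]]             # which.min: earliest tie
  }, integer(1))
}

#' Select one R-R interval from detected ED/ES frames
#'
#' @param edIndices,esIndices detections from [detectED()] / [detectES()].
#' @param policy `"first"` (default) returns the earliest valid
#'   (ED, ES, ED) triple; `"manual"` validates and returns `manual`.
#' @param manual integer c(edStart, es, edEnd) for `policy = "manual"`.
#' @return an [RRInterval-class].
#' @export
selectRR <- function(edIndices, esIndices, policy = c("first", "manual"),
                     manual = NULL) {
  policy <- match.arg(policy)
  if (policy == "manual") {
    stopifnot(length(manual) == 3L)
    return(new("RRInterval", edStart = as.integer(manual[1]),
               es = as.integer(manual[2]), edEnd = as.integer(manual[3])))
  }
  for (k in seq_len(length(edIndices) - 1L)) {
    a <- edIndices[k]; b <- edIndices[k + 1L]
    es <- esIndices[esIndices > a & esIndices < b]
    if (length(es)) {
      rr <- try(new("RRInterval", edStart = as.integer(a),
                    es = as.integer(es[1]), edEnd = as.integer(b)),
                silent = TRUE)
      if (!inherits(rr, "try-error")) return(rr)
    }
  }
  stop("no valid (ED, ES, ED) triple among the detections")
}

#' Compare automated and manual timeframe selections
#'
#' Matches detections to manual picks by nearest-neighbour within a ±`window`
#' frame window, one-to-one (ties broken toward the earlier pair), and
#' summarizes the matched differences deltaT = T_automatic - T_manual by
#' their mean and sample SD. Unmatched detections on either side are counted
#' separately.
#'
#' @param auto,manual sorted integer frame indices.
#' @param window matching half-width in frames (default 5).
#' @return list with `delta` (matched differences, auto - manual),
#'   `meanDelta`, `sdDelta`, `nMatched`, `unmatchedAuto`, `unmatchedManual`.
#' @export
compareDetections <- function(auto, manual, window = 5L) {
  stopifnot(!is.unsorted(auto), !is.unsorted(manual))
  pairs <- expand.grid(a = seq_along(auto), m = seq_along(manual))
  if (nrow(pairs)) {
    pairs$d <- abs(auto[pairs$a] - manual[pairs$m])
    pairs <- pairs[pairs$d <= window, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$a, pairs$m), , drop = FALSE]
  }
  usedA <- logical(length(auto)); usedM <- logical(length(manual))
  delta <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; m <- pairs$m[r]
    if (!usedA[a] && !usedM[m]) {
      usedA[a] <- TRUE; usedM[m] <- TRUE
      delta <- c(delta, auto[a] - manual[m])
    }
  }
  list(delta = delta,
       meanDelta = if (length(delta)) mean(delta) else NA_real_,
       sdDelta = if (length(delta) > 1L) stats::sd(delta) else
         if (length(delta) == 1L) 0 else NA_real_,
       nMatched = length(delta),
       unmatchedAuto = sum(!usedA),
       unmatchedManual = sum(!usedM))
}
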