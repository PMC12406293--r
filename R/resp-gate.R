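#' Specify a rectangular diaphragm region of interest
#'
#' Pixel ranges are 1-based and inclusive, following R convention.
#'
#' @param slice slice position index the ROI was placed on.
#' @param rowRange,colRange integer ranges c(first, last), inclusive.
#' @return a list of class `RoiSpec`.
#' @export
roiSpec <- function(slice, rowRange, colRange) {
  stopifnot(length(rowRange) == 2L, length(colRange) == 2L,
            rowRange[1] <= rowRange[2], colRange[1] <= colRange[2],
            rowRange[1] >= 1L, colRange[1] >= 1L)
  structure(list(slice = as.integer(slice),
                 rowRange = as.integer(rowRange),
                 colRange = as.integer(colRange)),
            class = "RoiSpec")
}

#' Extract the per-frame diaphragm ROI matrix
#'
#' Flattens the ROI of every timeframe into one row of a frames x pixels
#' matrix and normalizes the whole matrix to zero mean, unit variance. If all
#' frames are identical the variance scaling is skipped with a warning.
#'
#' @param series rows x cols x frames array (one slice's time series).
#' @param roi a [roiSpec()].
#' @return numeric matrix, n_frames x n_roi_pixels.
#' @export
extractRoiMatrix <- function(series, roi) {
  stopifnot(length(dim(series)) == 3L, inherits(roi, "RoiSpec"))
  d <- dim(series)
  if (roi$rowRange[2] > d[1] || roi$colRange[2] > d[2])
    stop("ROI rows ", roi$rowRange[1], "-", roi$rowRange[2], ", cols ",
         roi$colRange[1], "-", roi$colRange[2],
         " outside image bounds ", d[1], " x ", d[2])
  sub <- series[roi$rowRange[1]:roi$rowRange[2],
                roi$colRange[1]:roi$colRange[2], , drop = FALSE]
  m <- t(matrix(sub, ncol = d[3]))
  if (d[3] > 1L && all(m[-1, ] == rep(m[1, ], each = d[3] - 1L)))
    warning("all frames are identical within the ROI; the embedding will ",
            "be degenerate")
  mu <- mean(m); sdv <- stats::sd(as.vector(m))
  if (!is.finite(sdv) || sdv == 0) {
    warning("ROI intensities are constant; skipping variance scaling")
    m - mu
  } else (m - mu) / sdv
}

#' One-dimensional spectral embedding of the ROI time series
#'
#' Laplacian-eigenmaps-style embedding: a symmetric k-nearest-neighbour graph
#' (Euclidean distances between frame vectors, binary weights), whose
#' graph-Laplacian eigenvector for the smallest nonzero eigenvalue gives one
#' coordinate per timeframe tracking diaphragm position. The output is scaled
#' to unit SD; its sign is arbitrary until [orientForExpiration()].
#'
#' @param mat frames x pixels matrix from [extractRoiMatrix()].
#' @param kNeighbors neighbourhood size; default max(10, 5\% of frames).
#' @param dtMs temporal resolution (ms), carried along for peak detection.
#' @return an unoriented [RespiratorySignal-class].
#' @export
embedRespiratory <- function(mat, kNeighbors = NULL, dtMs = NA_real_) {
  stopifnot(is.matrix(mat))
  n <- nrow(mat)
  if (is.null(kNeighbors)) kNeighbors <- max(10L, ceiling(0.05 * n))
  kNeighbors <- as.integer(kNeighbors)
  if (n < kNeighbors + 1L)
    stop("need at least kNeighbors + 1 = ", kNeighbors + 1L, " frames, got ", n)

  dmat <- as.matrix(stats::dist(mat))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(kNeighbors + 1L)]   # skip self
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                             # symmetric union, binary

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("k-NN graph is disconnected (largest component ",
         max(comp$csize), " of ", n,
         " frames); increase kNeighbors")

  deg <- rowSums(adj)
  lap <- diag(deg) - adj
  eig <- eigen(lap, symmetric = TRUE)
  v <- eig$vectors[, n - 1L]                      # smallest nonzero eigenvalue
  sdv <- stats::sd(v)
  values <- if (sdv > 0) v / sdv else v

  ac1 <- tryCatch(stats::cor(values[-1], values[-n]), error = function(e) NA)
  if (!is.na(ac1) && ac1 < 0.5)
    warning("respiratory embedding has low lag-1 autocorrelation (",
            round(ac1, 2), "); the ROI may lack coherent motion")

  new("RespiratorySignal", values = as.numeric(values), oriented = FALSE,
      peaks = integer(0), dtMs = as.numeric(dtMs))
}

#' Orient the respiratory surrogate so peaks mean end-expiration
#'
#' The embedding sign is arbitrary. The heuristic correlates the signal with
#' the row-coordinate centroid of supra-median intensity inside the ROI (the
#' bright subdiaphragmatic tissue): at end-expiration the diaphragm sits
#' cranially (smaller row index), so the oriented signal must be
#' anti-correlated with the centroid row. An explicit `override` (+1 keep,
#' -1 flip) wins over the heuristic.
#'
#' @param signal an unoriented [RespiratorySignal-class].
#' @param series the slice time series the signal came from.
#' @param roi the same [roiSpec()].
#' @param override NULL (use heuristic) or +1 / -1 applied to the raw values.
#' @return an oriented [RespiratorySignal-class].
#' @export
orientForExpiration <- function(signal, series, roi, override = NULL) {
  stopifnot(is(signal, "RespiratorySignal"))
  n <- length(signal@values)
  if (dim(series)[3] != n)
    stop("signal length ", n, " does not match series frames ", dim(series)[3])

  if (!is.null(override)) {
    stopifnot(override %in% c(-1, 1))
    sgn <- override
  } else {
    sub <- series[roi$rowRange[1]:roi$rowRange[2],
                  roi$colRange[1]:roi$colRange[2], , drop = FALSE]
    med <- stats::median(sub)
    rowIdx <- seq.int(roi$rowRange[1], roi$rowRange[2])
    centroid <- vapply(seq_len(n), function(f) {
      fr <- sub[, , f]
      w <- fr >= med
      if (!any(w)) return(NA_real_)
      mean(rowIdx[row(fr)[w]])
    }, numeric(1))
    cc <- stats::cor(signal@values, centroid, use = "complete.obs")
    if (!is.finite(cc) || abs(cc) < 0.3)
      stop("orientation heuristic is inconclusive (|correlation| = ",
           round(abs(cc), 2), " < 0.3); pass override = +1 or -1")
    # end-expiration = cranial diaphragm = small centroid row = signal peak
    sgn <- if (cc > 0) -1 else 1
  }
  new("RespiratorySignal", values = sgn * signal@values, oriented = TRUE,
      peaks = integer(0), dtMs = signal@dtMs)
}

# strict local maxima of the smoothed signal, with a minimum peak separation
# (greedy by peak height); candidates below the median are noise wiggles in
# the inspiratory trough, not end-expiratory extremes
.findRespPeaks <- function(values, smoothWindow, minSeparation) {
  sm <- if (smoothWindow > 1L)
    stats::filter(values, rep(1 / smoothWindow, smoothWindow), sides = 2)
  else values
  sm <- as.numeric(sm)
  n <- length(sm)
  cand <- which(!is.na(sm) &
                c(NA, sm[-n]) < sm & sm > c(sm[-1], NA) &
                sm >= stats::median(sm, na.rm = TRUE))
  if (length(cand) > 1L && minSeparation > 1L) {
    keep <- logical(length(cand))
    for (i in order(sm[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[i]) < minSeparation)) keep[i] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  cand
}

#' Detect end-expiratory peaks in an oriented respiratory signal
#'
#' Strict local maxima of the moving-average smoothed signal, thinned to a
#' minimum separation (greedily, keeping higher peaks). Returns the signal
#' with its `peaks` slot filled.
#'
#' @inheritParams selectEndExpiratoryFrames
#' @return the [RespiratorySignal-class] with peaks recorded.
#' @export
detectRespPeaks <- function(signal, smoothWindow = 3L, minSeparation = NULL) {
  stopifnot(is(signal, "RespiratorySignal"))
  if (!signal@oriented)
    stop("signal must be oriented first (orientForExpiration)")
  if (is.null(minSeparation)) {
    minSeparation <- if (is.finite(signal@dtMs))
      as.integer(round(1500 / signal@dtMs)) else 10L
  }
  pk <- .findRespPeaks(signal@values, as.integer(smoothWindow),
                       as.integer(minSeparation))
  initialize(signal, peaks = as.integer(pk))
}

#' Suggest end-expiratory timeframe sets, best first
#'
#' For every detected end-expiratory peak, finds the maximal run of
#' consecutive frames containing the peak whose values stay within
#' `toleranceFrac` of the signal amplitude below the peak value, and returns
#' one [GatedSelection-class] per peak, ordered by decreasing run length
#' (ties toward the earlier peak). These are the "suggested sets" a user
#' chooses between in the interactive workflow.
#'
#' @inheritParams selectEndExpiratoryFrames
#' @return list of [GatedSelection-class], longest run first.
#' @export
suggestSelections <- function(signal, toleranceFrac = 0.15,
                              smoothWindow = 3L, minSeparation = NULL) {
  stopifnot(is(signal, "RespiratorySignal"))
  if (!signal@oriented)
    stop("signal must be oriented first (orientForExpiration)")
  v <- signal@values
  n <- length(v)
  if (is.null(minSeparation)) {
    minSeparation <- if (is.finite(signal@dtMs))
      as.integer(round(1500 / signal@dtMs)) else 10L
  }
  peaks <- .findRespPeaks(v, as.integer(smoothWindow),
                          as.integer(minSeparation))
  if (length(peaks) == 0L)
    stop("no end-expiratory peak detected; the signal may be monotone or ",
         "too short")
  amp <- max(v) - min(v)
  runs <- lapply(peaks, function(pk) {
    thr <- v[pk] - toleranceFrac * amp
    lo <- pk
    while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
    hi <- pk
    while (hi < n && v[hi + 1L] >= thr) hi <- hi + 1L
    lo:hi
  })
  ord <- order(-lengths(runs), peaks)
  lapply(ord, function(i)
    new("GatedSelection", peak = as.integer(peaks[i]),
        frames = as.integer(runs[[i]]), values = v[runs[[i]]]))
}

#' Select the best set of end-expiratory timeframes
#'
#' Detects end-expiratory peaks (strict local maxima of the moving-average
#' smoothed signal with a minimum separation reflecting a plausible breathing
#' rate), then, for every peak, finds the maximal run of consecutive frames
#' containing it whose values stay within `toleranceFrac` of the signal
#' amplitude below the peak value. The peak whose run holds the most frames
#' wins; ties go to the earliest peak.
#'
#' @param signal an oriented [RespiratorySignal-class].
#' @param toleranceFrac tolerance band as a fraction of the signal amplitude
#'   (max - min); default 0.15.
#' @param smoothWindow moving-average window (frames) for peak detection;
#'   default 3. Use 1 for no smoothing.
#' @param minSeparation minimum frames between peaks; default 1.5 s worth of
#'   frames when the signal knows its dtMs (breathing is not expected above
#'   40/min), else 10.
#' @param minRun minimum acceptable run length; selections at or below ~20
#'   frames rarely contain a full cardiac cycle. Set 0 to disable.
#' @return a [GatedSelection-class].
#' @export
selectEndExpiratoryFrames <- function(signal, toleranceFrac = 0.15,
                                      smoothWindow = 3L,
                                      minSeparation = NULL,
                                      minRun = 20L) {
  sug <- suggestSelections(signal, toleranceFrac, smoothWindow, minSeparation)
  best <- sug[[1]]
  if (length(best@frames) < minRun)
    stop("best end-expiratory run has only ", length(best@frames),
         " frames (minimum ", minRun, "); increase toleranceFrac or ",
         "acquire more frames")
  best
}
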