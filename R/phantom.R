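#' Construct phantom parameters
#'
#' Builds a validated [PhantomParams-class]. Defaults emulate a patient-like
#' real-time exercise short-axis acquisition: 36 ms temporal resolution,
#' 1.9 x 2.8 mm in-plane spacing, 14 slice positions, 250 timeframes per
#' slice, heart rate 110 beats/min, and free breathing with a pronounced
#' end-expiratory pause.
#'
#' @param nSlices,nFrames,dtMs,pixelMm,sliceThicknessMm,grid acquisition
#'   geometry; see [PhantomParams-class].
#' @param heartRateBpm,hrJitterFrac,systoleFrac cardiac model parameters.
#' @param respRateBpm,respAmpPx respiratory model parameters.
#' @param rEndoEdMm,rEndoEsMm,ringAreaMm2 LV geometry at the basal level.
#' @param noiseSd additive Gaussian noise SD relative to myocardial intensity.
#' @param seed RNG seed.
#' @return a [PhantomParams-class] object.
#' @examples
#' p <- phantomParams(nSlices = 2L, nFrames = 60L, grid = c(48L, 48L))
#' @export
phantomParams <- function(nSlices = 14L, nFrames = 250L, dtMs = 36,
                          pixelMm = c(1.9, 2.8), sliceThicknessMm = 8,
                          grid = c(96L, 96L),
                          heartRateBpm = 110, hrJitterFrac = 0.05,
                          systoleFrac = 1 / 3,
                          respRateBpm = 15, respAmpPx = 5,
                          rEndoEdMm = 22, rEndoEsMm = 14,
                          ringAreaMm2 = 1100,
                          noiseSd = 0.08, seed = 1L) {
  new("PhantomParams",
      nSlices = as.integer(nSlices), nFrames = as.integer(nFrames),
      dtMs = as.numeric(dtMs), pixelMm = as.numeric(pixelMm),
      sliceThicknessMm = as.numeric(sliceThicknessMm),
      grid = as.integer(grid),
      heartRateBpm = as.numeric(heartRateBpm),
      hrJitterFrac = as.numeric(hrJitterFrac),
      systoleFrac = as.numeric(systoleFrac),
      respRateBpm = as.numeric(respRateBpm),
      respAmpPx = as.numeric(respAmpPx),
      rEndoEdMm = as.numeric(rEndoEdMm), rEndoEsMm = as.numeric(rEndoEsMm),
      ringAreaMm2 = as.numeric(ringAreaMm2),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# bSSFP-like intensity ordering: blood > liver > myocardium > background
.phantomIntensity <- list(background = 0.05, myocardium = 0.5,
                          blood = 1.0, liver = 0.8)

# myocardial density, g/mL (standard CMR convention)
.myocardialDensity <- 1.05

#' Endocardial radius waveform over the cardiac cycle
#'
#' Asymmetric contraction with a faster systolic limb from ED (phase 0) to
#' ES (phase `systoleFrac`) and a slower diastolic limb back to ED. Each
#' limb mixes a half-cosine with a linear ramp (30/70 systole, 50/50
#' diastole): ejection starts promptly at ED and filling continues right up
#' to the next ED (exercise physiology has no diastasis), so the radius has
#' a unique, well-separated maximum each cycle even after rasterization,
#' with the systolic downslope at ED markedly steeper than the diastolic
#' upslope into it.
#'
#' @param phase cardiac phase in [0, 1), 0 = ED.
#' @param rEd,rEs radii at ED and ES.
#' @param systoleFrac fraction of the period from ED to ES.
#' @return radius at each phase.
#' @keywords internal
.radiusAtPhase <- function(phase, rEd, rEs, systoleFrac) {
  r <- numeric(length(phase))
  sys <- phase <= systoleFrac
  v <- phase[sys] / systoleFrac
  r[sys] <- rEs + (rEd - rEs) * (0.3 * (1 + cos(pi * v)) / 2 + 0.7 * (1 - v))
  dia <- !sys
  u <- (phase[dia] - systoleFrac) / (1 - systoleFrac)
  r[dia] <- rEs + (rEd - rEs) * ((1 - cos(pi * u)) / 4 + u / 2)
  r
}

# inspiratory excursion in [0,1]: raised-cosine squared, giving a long flat
# end-expiratory plateau (expiratory pause) and a brief inspiratory bump
.respWaveform <- function(tSec, periodSec, phaseOffset) {
  ((1 - cos(2 * pi * (tSec / periodSec - phaseOffset))) / 2)^2
}

#' Generate a synthetic free-breathing real-time short-axis stack
#'
#' Renders a multi-slice, multi-heartbeat real-time acquisition with known
#' ground truth. The LV is a bright-blood disk (endocardium) inside a
#' mid-intensity myocardial annulus whose outer radius is set each frame so
#' the annulus area equals `ringAreaMm2` exactly (incompressible myocardium);
#' a bright liver half-plane below the heart provides a diaphragm edge that
#' translates with respiration. Slices are independent time series with
#' random cardiac and respiratory phase offsets, as in sequential slice
#' acquisition; per-slice radii follow an apex-to-base scaling profile.
#'
#' @param params a [PhantomParams-class].
#' @return list with elements `stack` ([RealTimeStack-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomParams(nSlices = 2L, nFrames = 40L,
#'                                     grid = c(48L, 48L)))
#' nSlices(ph$stack)
#' @export
generatePhantom <- function(params) {
  validObject(params)
  p <- params
  rows <- p@grid[1]; cols <- p@grid[2]
  rowMm <- p@pixelMm[1]; colMm <- p@pixelMm[2]
  pixArea <- rowMm * colMm
  intens <- .phantomIntensity

  # apex (slice 1) to base scaling of the endocardial radius
  profile <- if (p@nSlices == 1L) 1 else seq(0.7, 1.0, length.out = p@nSlices)

  # sizing check: largest epicardial radius (ED, basal slice) plus the
  # respiratory excursion must fit inside the grid with a margin
  rEpiMax <- sqrt(p@ringAreaMm2 / pi + p@rEndoEdMm^2)
  needRows <- 2 * rEpiMax / rowMm + p@respAmpPx + 6
  needCols <- 2 * rEpiMax / colMm + 6
  if (rows < needRows || cols < needCols)
    stop("grid ", rows, " x ", cols, " too small: the epicardium plus ",
         "respiratory excursion needs at least ", ceiling(needRows), " x ",
         ceiling(needCols),
         " pixels; enlarge `grid` or reduce radii/respAmpPx")

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(p@seed)

  t0Beat <- 60000 / p@heartRateBpm            # mean cardiac period, ms
  respPeriodSec <- 60 / p@respRateBpm
  dtSec <- p@dtMs / 1000
  totalMs <- (p@nFrames - 1L) * p@dtMs

  # heart centred in-plane, shifted up to leave room for the diaphragm
  heartRow0 <- rows / 2 - p@respAmpPx / 2 - 2
  heartCol0 <- cols / 2 + 0.5
  diaphRow0 <- heartRow0 + rEpiMax / rowMm + 4   # edge row at end-expiration

  rowIdx <- seq_len(rows); colIdx <- seq_len(cols)

  slices <- vector("list", p@nSlices)
  respD <- vector("list", p@nSlices)
  phases <- vector("list", p@nSlices)
  edL <- vector("list", p@nSlices)
  esL <- vector("list", p@nSlices)
  endoL <- vector("list", p@nSlices)
  epiL <- vector("list", p@nSlices)

  edgeW <- 2.0                                   # disk anti-aliasing width, mm
  edgeWLiver <- 2.0                              # diaphragm edge width, mm

  for (s in seq_len(p@nSlices)) {
    rEd <- profile[s] * p@rEndoEdMm
    rEs <- profile[s] * p@rEndoEsMm

    # sub-pixel in-plane offset per slice: anatomy is never grid-aligned,
    # and a generic centre avoids degenerate rasterization steps
    ctrOff <- stats::runif(2, -0.5, 0.5)
    heartRowS <- heartRow0 + ctrOff[1]
    heartColS <- heartCol0 + ctrOff[2]
    colMmOff2 <- matrix(((colIdx - heartColS) * colMm)^2, rows, cols,
                        byrow = TRUE)

    # beat boundaries: enough jittered beats to cover the acquisition
    phi0 <- stats::runif(1)
    nBeats <- ceiling(totalMs / (t0Beat * (1 - p@hrJitterFrac))) + 3L
    periods <- t0Beat * (1 + p@hrJitterFrac * stats::runif(nBeats, -1, 1))
    bounds <- -phi0 * periods[1] + c(0, cumsum(periods))

    tMs <- (seq_len(p@nFrames) - 1L) * p@dtMs
    beat <- findInterval(tMs, bounds)            # which beat each frame is in
    phase <- (tMs - bounds[beat]) / periods[beat]

    # labelled ED frames: frame nearest each beat boundary inside the series;
    # bIdx[j] is the boundary (= beat start) index behind ed[j]
    bIdx <- which(bounds > -p@dtMs / 2 & bounds < totalMs + p@dtMs / 2)
    ed <- pmin(pmax(round(bounds[bIdx] / p@dtMs) + 1L, 1L), p@nFrames)
    keep <- !duplicated(ed)
    ed <- ed[keep]; bIdx <- bIdx[keep]
    # labelled ES frames: frame nearest each ES time, strictly between EDs
    es <- integer(0)
    if (length(ed) >= 2L) {
      for (k in seq_len(length(ed) - 1L)) {
        b <- bIdx[k]                             # beat b spans bounds[b]..bounds[b+1]
        esT <- bounds[b] + p@systoleFrac * periods[b]
        cand <- round(esT / p@dtMs) + 1L
        es <- c(es, min(max(cand, ed[k] + 1L), ed[k + 1L] - 1L))
      }
    }

    psi0 <- stats::runif(1)
    disp <- p@respAmpPx * .respWaveform(tMs / 1000, respPeriodSec, psi0)

    rEndo <- .radiusAtPhase(phase, rEd, rEs, p@systoleFrac)

    img <- array(0, c(rows, cols, p@nFrames))
    endo <- array(FALSE, c(rows, cols, p@nFrames))
    epi <- array(FALSE, c(rows, cols, p@nFrames))

    for (f in seq_len(p@nFrames)) {
      cr <- heartRowS + disp[f]
      rowMmOff2 <- (rowIdx - cr)^2 * rowMm^2
      rho <- sqrt(matrix(rowMmOff2, rows, cols) + colMmOff2)
      # the epicardial radius is chosen per frame so the rasterized annulus
      # pixel count matches ringAreaMm2 (incompressible myocardium holds
      # exactly, up to pixel quantization, in the masks themselves)
      endoCount <- sum(rho <= rEndo[f])
      srt <- sort(rho, method = "quick")
      k <- round(endoCount + p@ringAreaMm2 / pixArea)
      rEpiF <- (srt[k] + srt[k + 1L]) / 2
      covEpi <- pmin(pmax((rEpiF - rho) / edgeW + 0.5, 0), 1)
      covEndo <- pmin(pmax((rEndo[f] - rho) / edgeW + 0.5, 0), 1)
      edgeRow <- diaphRow0 + disp[f]
      covLiver <- matrix(pmin(pmax((rowIdx - edgeRow) * rowMm / edgeWLiver + 0.5,
                                   0), 1), rows, cols)
      frame <- intens$background +
        (intens$liver - intens$background) * covLiver
      frame <- frame + (intens$myocardium - intens$background) * covEpi *
        (1 - covLiver)
      frame <- frame + (intens$blood - intens$myocardium) * covEndo
      img[, , f] <- frame
      endo[, , f] <- rho <= rEndo[f]
      epi[, , f] <- rho <= rEpiF
    }
    if (p@noiseSd > 0)
      img <- img + stats::rnorm(length(img),
                                sd = p@noiseSd * intens$myocardium)

    slices[[s]] <- img
    respD[[s]] <- disp
    phases[[s]] <- phase
    edL[[s]] <- as.integer(ed)
    esL[[s]] <- as.integer(es)
    endoL[[s]] <- endo
    epiL[[s]] <- epi
  }

  stack <- new("RealTimeStack", slices = slices, dtMs = p@dtMs,
               pixelMm = p@pixelMm, sliceThicknessMm = p@sliceThicknessMm)
  truth <- new("PhantomTruth",
               respDisplacement = respD, cardiacPhase = phases,
               edFrames = edL, esFrames = esL,
               endoMasks = endoL, epiMasks = epiL,
               trueMassG = p@ringAreaMm2 * p@nSlices * p@sliceThicknessMm *
                 .myocardialDensity / 1000,
               params = p)
  list(stack = stack, truth = truth)
}

#' Ground-truth endocardial area series for one phantom slice
#'
#' Rasterized endocardial mask area per timeframe (mm^2). By construction its
#' per-cycle maxima fall at the labelled ED frames, which makes it the oracle
#' input for the cardiac gating rules.
#'
#' @param truth a [PhantomTruth-class].
#' @param slice slice position index.
#' @return numeric vector, one area (mm^2) per timeframe.
#' @export
truthAreaSeries <- function(truth, slice) {
  stopifnot(is(truth, "PhantomTruth"))
  if (slice < 1L || slice > length(truth@endoMasks))
    stop("slice ", slice, " out of range 1..", length(truth@endoMasks))
  pixArea <- prod(truth@params@pixelMm)
  m <- truth@endoMasks[[slice]]
  apply(m, 3, sum) * pixArea
}

# save/restore the global RNG state so generatePhantom is self-contained
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
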