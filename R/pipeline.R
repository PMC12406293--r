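#' Run the full retrospective synchronization pipeline
#'
#' Per slice: extract the diaphragm ROI, embed it to a 1D respiratory
#' surrogate, orient it, select the best end-expiratory run, segment the LV
#' within that run, detect ED and ES from the area curve, and select one
#' R-R interval. Across slices: synchronize the R-R intervals. When
#' endo-/epicardial masks are supplied, the volume curve, the four analysis
#' phases (ED/MS/ES/ERF) and the per-phase mass table are computed as well.
#'
#' Every interactive step of the original workflow (ROI placement, peak
#' choice, ED/ES picks) is expressed as an argument so runs are scriptable
#' and deterministic. Stage errors are re-thrown with the slice index and
#' stage name attached.
#'
#' @param stack a [RealTimeStack-class].
#' @param roi a [roiSpec()]; the same in-plane rectangle is applied to every
#'   slice series.
#' @param kNeighbors,toleranceFrac,smoothWindow,minRun respiratory gating
#'   parameters (see [embedRespiratory()], [selectEndExpiratoryFrames()]).
#' @param orientOverride NULL, +1 or -1 (see [orientForExpiration()]).
#' @param segmenter,masks segmentation contract (see [segmentLV()]); `masks`
#'   here is a per-slice list of 3D arrays.
#' @param window ED detection neighbourhood half-width.
#' @param rrPolicy,rrManual R-R selection (see [selectRR()]); `rrManual` may
#'   be a per-slice list of triples.
#' @param endoMasks,epiMasks optional per-slice ground-truth or manual mask
#'   series enabling the volumetric analysis.
#' @param outDir optional directory: writes the cine, the JSON run report
#'   and CSV tables.
#' @return list with `selections`, `rr`, `cine`, `report`, and when masks
#'   were supplied `volumeCurve`, `phases`, `massTable`.
#' @export
runPipeline <- function(stack, roi,
                        kNeighbors = NULL, toleranceFrac = 0.15,
                        smoothWindow = 3L, minRun = 20L,
                        orientOverride = NULL,
                        segmenter = "reference", masks = NULL,
                        window = 3L,
                        rrPolicy = "first", rrManual = NULL,
                        endoMasks = NULL, epiMasks = NULL,
                        outDir = NULL) {
  stopifnot(is(stack, "RealTimeStack"))
  nS <- nSlices(stack)
  warningsLog <- character(0)
  collect <- function(expr, stage, slice) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "', slice ", slice, ": ",
             conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warningsLog <<- c(warningsLog,
                          paste0("[", stage, " slice ", slice, "] ",
                                 conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  selections <- vector("list", nS)
  rrs <- vector("list", nS)
  cines <- vector("list", nS)
  detections <- vector("list", nS)

  for (s in seq_len(nS)) {
    ser <- sliceData(stack, s)
    mat <- collect(extractRoiMatrix(ser, roi), "resp-gate", s)
    sig <- collect(embedRespiratory(mat, kNeighbors, dtMs = dtMs(stack)),
                   "resp-gate", s)
    sig <- collect(orientForExpiration(sig, ser, roi, orientOverride),
                   "resp-gate", s)
    suggestions <- collect(suggestSelections(sig, toleranceFrac, smoothWindow),
                           "resp-gate", s)
    suggestions <- Filter(function(x) length(gatedFrames(x)) >= minRun,
                          suggestions)
    if (!length(suggestions))
      stop("stage 'resp-gate', slice ", s, ": no end-expiratory run of at ",
           "least ", minRun, " frames", call. = FALSE)

    # the interactive workflow lets the user pick among the suggested sets;
    # here the suggestions are tried longest-run first, moving on when a set
    # holds no full R-R interval, and failing only when all sets fail
    done <- FALSE
    lastErr <- NULL
    for (sel in suggestions) {
      res <- tryCatch({
        gated <- ser[, , gatedFrames(sel), drop = FALSE]
        mk <- segmentLV(gated,
                        segmenter = if (!is.null(masks)) "masks" else segmenter,
                        masks = if (!is.null(masks))
                          masks[[s]][, , gatedFrames(sel), drop = FALSE])
        series <- areaSeries(mk, prod(pixelSpacing(stack)),
                             frames = gatedFrames(sel))
        ed <- collect(detectED(series, window), "cardiac-gate", s)
        es <- detectES(series, ed)
        rr <- selectRR(ed, es, rrPolicy,
                       manual = if (is.list(rrManual)) rrManual[[s]]
                                else rrManual)
        list(sel = sel, ed = ed, es = es, rr = rr)
      }, error = function(e) e)
      if (!inherits(res, "error")) {
        selections[[s]] <- res$sel
        detections[[s]] <- list(ed = res$ed, es = res$es)
        rrs[[s]] <- res$rr
        cines[[s]] <- sliceCine(stack, s, res$rr)
        done <- TRUE
        break
      } else lastErr <- res
    }
    if (!done)
      stop("stage 'cardiac-gate', slice ", s, ": all ",
           length(suggestions), " suggested end-expiratory sets failed; ",
           "last error: ", conditionMessage(lastErr), call. = FALSE)
  }

  cine <- if (nS >= 2L) synchronize(cines) else NULL

  report <- list(
    nSlices = nS,
    respiratory = lapply(selections, function(x)
      list(peak = gatedPeak(x), firstFrame = min(gatedFrames(x)),
           lastFrame = max(gatedFrames(x)), nFrames = length(gatedFrames(x)))),
    detections = detections,
    rr = lapply(rrs, function(x)
      list(edStart = x@edStart, es = x@es, edEnd = x@edEnd)),
    nSys = if (!is.null(cine)) nSys(cine) else NA,
    nDia = if (!is.null(cine)) nDia(cine) else NA,
    warnings = warningsLog)

  out <- list(selections = selections, rr = rrs, cine = cine,
              report = report)

  if (!is.null(cine) && !is.null(endoMasks)) {
    pixArea <- prod(pixelSpacing(stack))
    alignedEndo <- alignMasks(cine, endoMasks)
    out$volumeCurve <- volumeCurve(alignedEndo, pixArea,
                                   sliceThickness(stack))
    out$phases <- identifyPhases(out$volumeCurve, nSys(cine))
    if (!is.null(epiMasks)) {
      alignedEpi <- alignMasks(cine, epiMasks)
      phaseIdx <- unlist(out$phases)
      mass <- vapply(phaseIdx, function(t)
        lvMass(lapply(seq_len(nS), function(sl) alignedEpi[, , sl, t]),
               lapply(seq_len(nS), function(sl) alignedEndo[, , sl, t]),
               pixArea, sliceThickness(stack)),
        numeric(1))
      vol <- out$volumeCurve[phaseIdx]
      out$massTable <- data.frame(phase = names(out$phases),
                                  frame = phaseIdx,
                                  volumeMl = vol, massG = mass,
                                  row.names = NULL)
    }
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cine)) writeCine(cine, outDir)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    sigCsv <- do.call(rbind, lapply(seq_len(nS), function(s) {
      sel <- selections[[s]]
      data.frame(slice = s, frame = gatedFrames(sel),
                 value = sel@values, selected = TRUE)
    }))
    utils::write.csv(sigCsv, file.path(outDir, "respiratory_selection.csv"),
                     row.names = FALSE)
    if (!is.null(out$massTable))
      utils::write.csv(out$massTable, file.path(outDir, "phase_mass.csv"),
                       row.names = FALSE)
    if (!is.null(out$volumeCurve))
      utils::write.csv(
        data.frame(timeIndex = seq_along(out$volumeCurve),
                   volumeMl = out$volumeCurve),
        file.path(outDir, "volume_curve.csv"), row.names = FALSE)
  }
  out
}
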