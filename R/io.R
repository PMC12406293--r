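#' Write a real-time stack to disk
#'
#' One NIfTI volume per slice position (rows x cols x time), written as
#' float64 so round-trips are exact, plus a `stack.json` sidecar with the
#' geometry (dtMs, pixel spacing, slice thickness, slice order) and, when
#' given, the phantom ground truth (frame labels, respiratory displacement,
#' true mass). Mask volumes are written alongside when truth is included.
#'
#' @param stack a [RealTimeStack-class].
#' @param dir output directory (created if needed).
#' @param truth optional [PhantomTruth-class] to persist with the stack.
#' @param writeMasks also write truth masks as NIfTI volumes (default TRUE
#'   when truth is given).
#' @return the directory, invisibly.
#' @export
writeStack <- function(stack, dir, truth = NULL, writeMasks = !is.null(truth)) {
  stopifnot(is(stack, "RealTimeStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nS <- nSlices(stack)
  for (s in seq_len(nS)) {
    img <- RNifti::asNifti(
      sliceData(stack, s),
      reference = list(pixdim = c(1, stack@pixelMm, stack@dtMs, 1, 1, 1, 1)),
      datatype = "double")
    RNifti::writeNifti(img, file.path(dir, sprintf("slice_%03d.nii", s)))
    if (writeMasks && !is.null(truth)) {
      RNifti::writeNifti(
        RNifti::asNifti(truth@endoMasks[[s]] + 0, datatype = "double"),
        file.path(dir, sprintf("endo_%03d.nii", s)))
      RNifti::writeNifti(
        RNifti::asNifti(truth@epiMasks[[s]] + 0, datatype = "double"),
        file.path(dir, sprintf("epi_%03d.nii", s)))
    }
  }
  side <- list(nSlices = nS, dtMs = stack@dtMs, pixelMm = stack@pixelMm,
               sliceThicknessMm = stack@sliceThicknessMm,
               sliceOrder = "apex-to-base")
  if (!is.null(truth))
    side$truth <- list(
      edFrames = truth@edFrames, esFrames = truth@esFrames,
      respDisplacement = truth@respDisplacement,
      cardiacPhase = truth@cardiacPhase,
      trueMassG = truth@trueMassG)
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a real-time stack from disk
#'
#' Accepts either a directory written by [writeStack()] (per-slice
#' `slice_*.nii` volumes plus `stack.json`) or a single 4D NIfTI file whose
#' third axis indexes slices and fourth axis time. Missing geometry metadata
#' is filled from documented defaults with a warning (dtMs 36 ms, spacing
#' 1.9 x 2.8 mm, thickness 8 mm).
#'
#' @param path directory or 4D NIfTI file.
#' @return a [RealTimeStack-class].
#' @export
loadStack <- function(path) {
  defaults <- list(dtMs = 36, pixelMm = c(1.9, 2.8), sliceThicknessMm = 8)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^slice_[0-9]+\\.nii$",
                             full.names = TRUE))
    if (!length(files)) stop("no slice_*.nii volumes in ", path)
    sidecar <- file.path(path, "stack.json")
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                          simplifyVector = TRUE)
            else list()
    slices <- lapply(files, function(f) {
      a <- as.array(RNifti::readNifti(f))
      attributes(a) <- list(dim = dim(a))
      a
    })
  } else {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) != 4L)
      stop("single-file input must be a 4D volume (rows x cols x slices x ",
           "time), got ", length(dim(a)), " dimensions")
    meta <- list()
    slices <- lapply(seq_len(dim(a)[3]), function(s) {
      x <- a[, , s, , drop = TRUE]
      dim(x) <- dim(a)[c(1, 2, 4)]
      x
    })
  }
  for (f in names(defaults)) {
    if (is.null(meta[[f]])) {
      warning("metadata '", f, "' missing; using default ",
              paste(defaults[[f]], collapse = " x "))
      meta[[f]] <- defaults[[f]]
    }
  }
  new("RealTimeStack", slices = slices, dtMs = as.numeric(meta$dtMs),
      pixelMm = as.numeric(meta$pixelMm),
      sliceThicknessMm = as.numeric(meta$sliceThicknessMm))
}

#' Write a synchronized cine and its provenance
#'
#' The cine goes out as one 4D NIfTI (rows x cols x slices x time) and the
#' sidecar JSON records nSys, nDia, geometry and the full per-frame source
#' mapping (slice, source frame indices, interpolation weights).
#'
#' @param cine a [SynchronizedCine-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeCine <- function(cine, dir) {
  stopifnot(is(cine, "SynchronizedCine"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(cine@data, datatype = "double")
  RNifti::writeNifti(img, file.path(dir, "cine.nii"))
  jsonlite::write_json(
    list(nSys = cine@nSys, nDia = cine@nDia,
         pixelMm = cine@pixelMm, sliceThicknessMm = cine@sliceThicknessMm,
         provenance = cine@provenance),
    file.path(dir, "cine.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
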