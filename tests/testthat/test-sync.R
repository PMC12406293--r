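# builds a SliceCine whose pixel values encode (slice, frame) so that
# resampling arithmetic is directly checkable
codedCine <- function(len, esOffset, slice = 1L, rows = 4L, cols = 3L,
                      base = 0) {
  frames <- array(0, c(rows, cols, len))
  for (f in seq_len(len)) frames[, , f] <- base + f
  new("SliceCine", slice = as.integer(slice), frames = frames,
      esOffset = as.integer(esOffset),
      sourceFrames = seq_len(len) + 100L * as.integer(slice),
      dtMs = 36, pixelMm = c(1.9, 2.8), sliceThicknessMm = 8)
}

test_that("interval splitting shares the ES frame between both limbs", {
  cine <- codedCine(12L, 5L)            # ES the fifth frame of twelve
  limbs <- splitIntervals(cine)
  expect_equal(dim(limbs$systolic)[3], 5L)
  expect_equal(dim(limbs$diastolic)[3], 8L)
  expect_identical(limbs$systolic[, , 5], limbs$diastolic[, , 1])
  # concatenating the limbs minus one shared ES reproduces the input
  glued <- array(c(limbs$systolic, limbs$diastolic[, , -1]), dim(cine@frames))
  expect_identical(glued, cine@frames)

  minimal <- codedCine(3L, 2L)
  lm <- splitIntervals(minimal)
  expect_equal(c(dim(lm$systolic)[3], dim(lm$diastolic)[3]), c(2L, 2L))
})

test_that("boundary ES offsets violate the slice-cine invariant", {
  expect_error(codedCine(5L, 1L), "esOffset")
  expect_error(codedCine(5L, 5L), "esOffset")
})

test_that("temporal resampling matches hand-computed interpolation", {
  expect_equal(resampleTime(c(0, 1, 2, 3, 4), 3L), c(0, 2, 4))
  expect_equal(resampleTime(c(0, 3, 6, 9), 3L), c(0, 4.5, 9))
  x <- rnorm(7)
  expect_identical(resampleTime(x, 7L), x)       # identity is bit-exact
  expect_error(resampleTime(c(1, 2, 3), 5L), "down-sampling")
  expect_error(resampleTime(c(1, 2, 3), 1L), "nTarget")
})

test_that("resampling preserves endpoints exactly and never reorders", {
  set.seed(12)
  frames <- array(rnorm(6 * 5 * 11), c(6, 5, 11))
  out <- resampleTime(frames, 4L)
  expect_identical(out[, , 1], frames[, , 1])
  expect_identical(out[, , 4], frames[, , 11])
  pos <- cineRT:::.samplePositions(11L, 4L)
  expect_true(all(diff(pos) > 0))
})

test_that("synchronization resamples to the across-slice minima", {
  # per-slice (systolic, diastolic) counts (10,20), (8,18), (9,22)
  cines <- list(codedCine(29L, 10L, slice = 1L),
                codedCine(25L, 8L, slice = 2L),
                codedCine(30L, 9L, slice = 3L))
  sc <- synchronize(cines)
  expect_equal(nSys(sc), 8L)
  expect_equal(nDia(sc), 18L)
  expect_equal(dim(cineData(sc))[4], 25L)        # nSys + nDia - 1

  # ED and ES of every slice appear unmodified at the aligned indices
  for (s in 1:3) {
    expect_identical(cineData(sc)[, , s, 1], cines[[s]]@frames[, , 1])
    expect_identical(cineData(sc)[, , s, 8],
                     cines[[s]]@frames[, , cines[[s]]@esOffset])
    len <- dim(cines[[s]]@frames)[3]
    expect_identical(cineData(sc)[, , s, 25], cines[[s]]@frames[, , len])
  }

  # provenance sample times strictly increase for each slice
  pr <- provenance(sc)
  for (s in 1:3)
    expect_true(all(diff(pr$sampleTime[pr$slice == s]) > 0))
})

test_that("slices already at the minima pass through bit-identically", {
  cines <- list(codedCine(10L, 4L, slice = 1L),
                codedCine(10L, 4L, slice = 2L, base = 50))
  sc <- synchronize(cines)
  expect_equal(nSys(sc), 4L)
  expect_equal(nDia(sc), 7L)
  for (s in 1:2)
    expect_identical(cineData(sc)[, , s, ], cines[[s]]@frames)
})

test_that("re-synchronizing a synchronized cine is the identity", {
  cines <- list(codedCine(29L, 10L, slice = 1L),
                codedCine(25L, 8L, slice = 2L),
                codedCine(30L, 9L, slice = 3L))
  sc <- synchronize(cines)
  sc2 <- synchronize(asSliceCines(sc))
  expect_identical(cineData(sc2), cineData(sc))
  expect_equal(nSys(sc2), nSys(sc))
  expect_equal(nDia(sc2), nDia(sc))
})

test_that("degenerate limbs are rejected with the slice index", {
  cines <- list(codedCine(29L, 10L, slice = 1L),
                codedCine(25L, 8L, slice = 2L))
  cines[[2]]@esOffset <- 24L            # diastolic limb of 2 frames is fine
  expect_s4_class(synchronize(cines), "SynchronizedCine")
  # but a 1-frame limb is impossible to build (validity) so check the
  # synchronize-level error via a hand-built invalid-ish object
  bad <- cines
  slot(bad[[2]], "esOffset", check = FALSE) <- 25L
  expect_error(synchronize(bad), "slice")
})

test_that("full phantom pipeline aligns volume extremes at ED and ES", {
  ph <- testPhantom("default")
  roi <- testRoi()
  res <- runPipeline(ph$stack, roi, endoMasks = ph$truth@endoMasks,
                     epiMasks = ph$truth@epiMasks)
  sc <- res$cine
  aligned <- alignMasks(sc, ph$truth@endoMasks)
  pixArea <- prod(pixelSpacing(ph$stack))
  for (s in seq_len(nSlices(sc))) {
    areas <- vapply(seq_len(dim(aligned)[4]),
                    function(t) sum(aligned[, , s, t]) * pixArea, numeric(1))
    # cavity maximal at the aligned ED, minimal at the aligned ES,
    # allowing one frame of detection tolerance in area terms
    expect_gte(areas[1], max(areas) * 0.95)
    expect_lte(areas[nSys(sc)], min(areas) * 1.08)
  }
})
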