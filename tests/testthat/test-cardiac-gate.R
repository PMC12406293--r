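test_that("ED/ES detection reproduces the worked area-series example", {
  areas <- c(7, 8, 9, 10, 9, 8, 7, 8, 9, 10, 9, 8, 7, 8, 9, 10, 9)
  ed <- detectED(areas)
  # maxima with a full 3-frame window on both sides: positions 4 and 10
  # (the final rise at position 16 lacks right-hand neighbours)
  expect_equal(ed, c(4L, 10L))
  expect_equal(detectES(areas, ed), 7L)
})

test_that("strictly monotone areas yield a NoRRInterval error", {
  expect_error(detectED(as.numeric(1:20)), class = "NoRRInterval")
})

test_that("equal-maxima plateaus are dropped with a warning", {
  areas <- c(1, 2, 3, 9, 9, 3, 2, 1, 2, 3, 9.5, 3, 2, 1, 2, 3, 9.4, 3, 2, 1)
  expect_warning(ed <- detectED(areas), "plateau")
  expect_false(any(ed %in% c(4L, 5L)))
})

test_that("detection agrees with the brute-force oracle on random series", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(20:200, 1)
    areas <- switch(sample(3, 1),
      rnorm(n),                                       # rough
      10 + 5 * sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, sd = 0.5),
      round(10 + 5 * sin(seq(0, 6 * pi, length.out = n)), 1))  # with ties
    oed <- oracleED(areas)
    ed <- tryCatch(suppressWarnings(detectED(areas)),
                   error = function(e) integer(0))
    if (length(oed) < 2L) {
      expect_length(ed, 0L)
    } else {
      expect_identical(ed, oed)
      expect_identical(detectES(areas, ed), oracleES(areas, ed))
    }
  }
})

test_that("ES ties break to the earliest frame", {
  areas <- c(1, 2, 3, 9, 5, 2, 2, 5, 9, 3, 2, 1)
  # symmetric V between the EDs with equal minima at positions 6 and 7
  ed <- detectED(areas)
  expect_equal(ed, c(4L, 9L))
  expect_equal(detectES(areas, ed), 6L)
})

test_that("exactly one ES is reported between consecutive EDs", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(30:120, 1)
    areas <- 10 + 5 * sin(seq(0, 8 * pi, length.out = n)) + rnorm(n, sd = 0.3)
    ed <- tryCatch(suppressWarnings(detectED(areas)),
                   error = function(e) integer(0))
    if (length(ed) < 2L) next
    es <- detectES(areas, ed)
    expect_length(es, length(ed) - 1L)
    expect_true(all(es > ed[-length(ed)] & es < ed[-1]))
  }
})

test_that("area series converts mask counts with the pixel area", {
  masks <- array(FALSE, c(20, 20, 3))
  masks[1:10, 1:10, 1] <- TRUE                 # 100 pixels
  a <- areaSeries(masks, 1.9 * 2.8)
  expect_equal(areaValues(a), c(100 * 5.32, 0, 0))

  # rasterized disk of radius 10 at 1 mm^2 pixels: within a perimeter band
  # of the analytic pi * 100
  disk <- array(outer(1:40, 1:40, function(r, c)
    (r - 20.3)^2 + (c - 20.6)^2 <= 100), c(40, 40, 1))
  da <- areaValues(areaSeries(disk, 1))
  expect_lt(abs(da - pi * 100), 2 * pi * 10)
})

test_that("the reference segmenter recovers phantom endocardial areas", {
  ph <- testPhantom("default")
  s <- 2                                        # mid-ventricular
  ed1 <- edFrames(ph$truth, s)[3]
  fr <- sliceData(ph$stack, s)[, , ed1, drop = FALSE]
  mk <- segmentLV(fr)
  segArea <- sum(mk) * prod(pixelSpacing(ph$stack))
  truthArea <- truthAreaSeries(ph$truth, s)[ed1]
  expect_lt(abs(segArea - truthArea) / truthArea, 0.05)
})

test_that("all-zero frames trigger the empty-mask error path", {
  frames <- array(0, c(16, 16, 4))
  expect_error(segmentLV(frames), "empty masks")
})

test_that("precomputed masks pass through unchanged", {
  frames <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  masks <- array(sample(c(TRUE, FALSE), 300, replace = TRUE), c(10, 10, 3))
  expect_identical(segmentLV(frames, segmenter = "masks", masks = masks),
                   masks)
  badMasks <- array(TRUE, c(5, 5, 3))
  expect_error(segmentLV(frames, segmenter = "masks", masks = badMasks),
               "do not match")
})

test_that("R-R selection honours the first-valid-triple policy", {
  expect_s4_class(rr <- selectRR(c(4L, 10L), 7L), "RRInterval")
  expect_equal(c(rr@edStart, rr@es, rr@edEnd), c(4L, 7L, 10L))

  # earliest triple wins even when later ones exist
  rr2 <- selectRR(c(4L, 10L, 16L), c(7L, 13L))
  expect_equal(c(rr2@edStart, rr2@es, rr2@edEnd), c(4L, 7L, 10L))

  # manual triples are validated
  expect_error(selectRR(c(4L, 10L), 7L, policy = "manual",
                        manual = c(10L, 7L, 4L)),
               "edStart < es < edEnd")
})

test_that("deltaT comparison matches hand-computed statistics", {
  eq <- compareDetections(c(4L, 10L), c(4L, 10L))
  expect_equal(eq$delta, c(0, 0))
  expect_equal(eq$meanDelta, 0)
  expect_equal(eq$sdDelta, 0)

  sh <- compareDetections(c(5L, 11L), c(4L, 10L))
  expect_equal(sh$delta, c(1, 1))
  expect_equal(sh$meanDelta, 1)
  expect_equal(sh$sdDelta, 0)

  far <- compareDetections(3L, 30L)
  expect_equal(far$nMatched, 0L)
  expect_equal(far$unmatchedAuto, 1L)
  expect_equal(far$unmatchedManual, 1L)

  three <- compareDetections(c(4L, 9L, 16L), c(3L, 10L, 15L))
  expect_equal(three$delta, c(1, -1, 1))
  expect_equal(three$meanDelta, 1 / 3)
  expect_equal(three$sdDelta, sd(c(1, -1, 1)))
})

test_that("phantom ED/ES recovery is exact under ideal conditions", {
  # jitter-free, noise-free, breath-free: detection on the segmented areas
  # must land on the truth labels in every slice
  ph <- testPhantom("ideal", nSlices = 3L, nFrames = 150L,
                    heartRateBpm = 100, hrJitterFrac = 0, noiseSd = 0,
                    respAmpPx = 0, seed = 6L)
  for (s in 1:3) {
    mk <- segmentLV(sliceData(ph$stack, s))
    a <- areaSeries(mk, prod(pixelSpacing(ph$stack)))
    ed <- suppressWarnings(detectED(a))
    es <- detectES(a, ed)
    te <- edFrames(ph$truth, s)
    ts <- esFrames(ph$truth, s)
    expect_true(all(vapply(ed, function(x) min(abs(te - x)) <= 1, logical(1))))
    expect_true(all(vapply(es, function(x) min(abs(ts - x)) <= 2, logical(1))))
  }
})

test_that("ED recall does not improve with added noise", {
  # common random numbers: one noise field scaled to each level
  base <- testPhantom("ideal", nSlices = 3L, nFrames = 150L,
                      heartRateBpm = 100, hrJitterFrac = 0, noiseSd = 0,
                      respAmpPx = 0, seed = 6L)
  s <- 2
  ser <- sliceData(base$stack, s)
  set.seed(17)
  z <- array(rnorm(length(ser)), dim(ser))
  te <- edFrames(base$truth, s)
  te <- te[te > 3 & te < dim(ser)[3] - 3]
  recall <- vapply(c(0, 0.05, 0.1, 0.2), function(ns) {
    noisy <- ser + ns * 0.5 * z
    ed <- tryCatch(suppressWarnings(
      detectED(areaSeries(segmentLV(noisy), prod(pixelSpacing(base$stack))))),
      error = function(e) integer(0))
    mean(vapply(te, function(x) any(abs(ed - x) <= 1), logical(1)))
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_equal(recall[1], 1)
})
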