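# builds a toy series in which a bright horizontal edge moves down by a
# known per-frame displacement; the embedding should recover that motion
edgeSeries <- function(disp, rows = 20L, cols = 12L, edge0 = 8) {
  n <- length(disp)
  ser <- array(0, c(rows, cols, n))
  for (f in seq_len(n)) {
    pos <- edge0 + disp[f]
    cov <- pmin(pmax(seq_len(rows) - pos + 0.5, 0), 1)
    ser[, , f] <- matrix(cov, rows, cols)
  }
  ser
}

test_that("ROI matrix has the frames-by-pixels shape contract", {
  ser <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  m <- extractRoiMatrix(ser, roiSpec(1L, c(2L, 5L), c(3L, 7L)))
  expect_equal(dim(m), c(10L, 4L * 5L))
  expect_equal(mean(m), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(m)), 1, tolerance = 1e-12)
})

test_that("out-of-bounds ROI is rejected", {
  ser <- array(0, c(8, 9, 10))
  expect_error(extractRoiMatrix(ser, roiSpec(1L, c(2L, 9L), c(3L, 7L))),
               "outside image bounds")
})

test_that("identical frames give equal rows and a degeneracy warning", {
  ser <- array(rep(matrix(rnorm(42), 6, 7), 5), c(6, 7, 5))
  expect_warning(m <- extractRoiMatrix(ser, roiSpec(1L, c(1L, 6L), c(1L, 7L))),
                 "identical")
  expect_true(all(apply(m, 2, function(x) length(unique(x)) == 1L)))
})

test_that("a monotone edge shift produces monotone frame distances", {
  ser <- edgeSeries(seq(0, 6, length.out = 25))
  m <- extractRoiMatrix(ser, roiSpec(1L, c(1L, 20L), c(1L, 12L)))
  d <- as.matrix(dist(m))[1, ]
  expect_true(all(diff(d) > 0))
})

test_that("embedding recovers a known 1D displacement", {
  disp <- 3 + 3 * sin(2 * pi * (1:120) / 40)
  ser <- edgeSeries(disp)
  m <- extractRoiMatrix(ser, roiSpec(1L, c(1L, 20L), c(1L, 12L)))
  # repeated cycles put identical frames in tight clusters; a roomier
  # neighbourhood keeps the graph connected across clusters
  sig <- embedRespiratory(m, kNeighbors = 20L)
  rho <- cor(respValues(sig), disp, method = "spearman")
  expect_gte(abs(rho), 0.95)
})

test_that("identical frames receive identical embedding coordinates", {
  disp <- c(0, 1, 2, 3, 2, 1, 0, 1, 2, 3, 2, 1, 0, 1, 2, 3)
  ser <- edgeSeries(disp)
  m <- extractRoiMatrix(ser, roiSpec(1L, c(1L, 20L), c(1L, 12L)))
  sig <- suppressWarnings(embedRespiratory(m, kNeighbors = 8L))
  v <- respValues(sig)
  same <- which(disp == 0)
  expect_equal(max(abs(v[same] - v[same][1])), 0, tolerance = 1e-8)
})

test_that("structureless input completes with a low-autocorrelation warning", {
  set.seed(31)
  m <- matrix(rnorm(60 * 24), 60, 24)
  expect_warning(sig <- embedRespiratory(m, kNeighbors = 10L),
                 "autocorrelation")
  expect_length(respValues(sig), 60L)
})

test_that("disconnected neighbour graphs are reported with component size", {
  m <- rbind(matrix(0, 10, 4), matrix(100, 14, 4)) +
    matrix(rnorm(24 * 4, sd = 0.01), 24, 4)
  expect_error(suppressWarnings(embedRespiratory(m, kNeighbors = 3L)),
               "disconnected.*14")
})

test_that("orientation flips so end-expiratory peaks are maxima", {
  ph <- testPhantom("default")
  ser <- sliceData(ph$stack, 1)
  roi <- testRoi()
  sig <- embedRespiratory(extractRoiMatrix(ser, roi), dtMs = 36)
  or1 <- orientForExpiration(sig, ser, roi)
  expect_true(isOriented(or1))
  # peaks of the oriented signal are end-expiration: minimal displacement
  sel <- selectEndExpiratoryFrames(or1)
  disp <- ph$truth@respDisplacement[[1]]
  amp <- max(disp) - min(disp)
  expect_lt(disp[gatedPeak(sel)], min(disp) + 0.1 * amp)

  # sign-invariance of the full orientation path
  neg <- initialize(sig, values = -respValues(sig))
  or2 <- orientForExpiration(neg, ser, roi)
  expect_equal(respValues(or1), respValues(or2))

  # an explicit override wins regardless of the heuristic
  ov <- orientForExpiration(sig, ser, roi, override = -1)
  expect_equal(respValues(ov), -respValues(sig))
})

test_that("inconclusive orientation requires an explicit override", {
  set.seed(7)
  ser <- array(rnorm(20 * 12 * 40), c(20, 12, 40))
  m <- extractRoiMatrix(ser, roiSpec(1L, c(1L, 20L), c(1L, 12L)))
  sig <- suppressWarnings(embedRespiratory(m, kNeighbors = 8L))
  expect_error(orientForExpiration(sig, ser, roiSpec(1L, c(1L, 20L), c(1L, 12L))),
               "override")
})

test_that("the worked tolerance-band example selects the wider peak", {
  v <- c(0, 1, 2, 3, 2, 1, 0, 1, 2, 3.1, 3.0, 2, 0)
  sig <- new("RespiratorySignal", values = v, oriented = TRUE,
             peaks = integer(0), dtMs = NA_real_)
  sel <- selectEndExpiratoryFrames(sig, toleranceFrac = 1.05 / 3.1,
                                   smoothWindow = 1L, minSeparation = 1L,
                                   minRun = 0L)
  # peak at index 4 (value 3) holds 3 frames in band; peak at index 10
  # (3.1) holds only 2
  expect_equal(gatedPeak(sel), 4L)
  expect_equal(gatedFrames(sel), 3:5)
})

test_that("a strictly monotone signal has no peak", {
  sig <- new("RespiratorySignal", values = as.numeric(1:30), oriented = TRUE,
             peaks = integer(0), dtMs = NA_real_)
  expect_error(selectEndExpiratoryFrames(sig, smoothWindow = 1L,
                                         minSeparation = 1L, minRun = 0L),
               "no end-expiratory peak")
})

test_that("short selections are refused below the minimum run length", {
  v <- c(0, 1, 2, 1, 0)
  sig <- new("RespiratorySignal", values = v, oriented = TRUE,
             peaks = integer(0), dtMs = NA_real_)
  expect_error(selectEndExpiratoryFrames(sig, toleranceFrac = 0.15,
                                         smoothWindow = 1L,
                                         minSeparation = 1L, minRun = 20L),
               "minimum 20")
})

test_that("increasing the tolerance never shortens the selected run", {
  ph <- testPhantom("default")
  ser <- sliceData(ph$stack, 2)
  roi <- testRoi()
  sig <- orientForExpiration(
    embedRespiratory(extractRoiMatrix(ser, roi), dtMs = 36), ser, roi)
  lens <- vapply(c(0.05, 0.1, 0.15, 0.2, 0.3),
                 function(tf) length(gatedFrames(
                   selectEndExpiratoryFrames(sig, toleranceFrac = tf,
                                             minRun = 0L))),
                 numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("unoriented signals are refused by selection and peak detection", {
  sig <- new("RespiratorySignal", values = sin(1:50), oriented = FALSE,
             peaks = integer(0), dtMs = NA_real_)
  expect_error(selectEndExpiratoryFrames(sig), "oriented")
  expect_error(detectRespPeaks(sig), "oriented")
})
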