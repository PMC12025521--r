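test_that("grayscale conversion uses the luma weights and passes gray through", {
  g <- matrix(runif(64), 8, 8)
  expect_identical(toGrayscale(g), g)
  rgb <- array(0.4, c(8, 8, 3))
  expect_equal(toGrayscale(rgb), matrix(0.4, 8, 8))
  set.seed(3)
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- 0.299 * rgb[i, j, 1] + 0.587 * rgb[i, j, 2] +
      0.114 * rgb[i, j, 3]
  expect_equal(toGrayscale(rgb), oracle, tolerance = 1e-12)
  expect_error(toGrayscale(array(1, c(4, 4, 2))), "channel")
})

test_that("the ROI scan recovers a constructed bright rectangle exactly", {
  px <- roiFixture()  # rows 21:60, cols 31:70 (1-based) at value 200
  box <- computeROI(px, roiParams(intensityThreshold = 50,
                                  verticalBand = c(0.2, 0.8)))
  expect_equal(roiCoords(box),
               c(left = 30L, right = 70L, top = 20L, bottom = 60L))
})

test_that("degenerate ROI inputs behave as specified", {
  expect_error(computeROI(matrix(0, 100, 100),
                          roiParams(intensityThreshold = 50)),
               "empty ROI")
  full <- computeROI(matrix(255, 80, 90), roiParams(intensityThreshold = 50))
  expect_equal(roiCoords(full),
               c(left = 0L, right = 90L, top = 0L, bottom = 80L))
  # tiny supra-threshold blob below the minimum area
  px <- matrix(0, 100, 100); px[50:51, 50:51] <- 200
  expect_error(computeROI(px, roiParams(intensityThreshold = 50,
                                        minRoiPx = 256L)), "smaller")
})

test_that("the centre-out scan agrees with a full-scan oracle on random fixtures", {
  set.seed(20260923)
  for (i in 1:60) {
    h <- sample(60:120, 1); w <- sample(60:120, 1)
    midR <- (h + 1) %/% 2; midC <- (w + 1) %/% 2
    top <- sample(5:midR, 1); bottom <- sample(midR:(h - 2), 1)
    left <- sample(5:midC, 1); right <- sample(midC:(w - 2), 1)
    px <- roiFixture(h, w, top, bottom, left, right,
                     value = runif(1, 80, 255), clutterMax = 40)
    p <- roiParams(intensityThreshold = 50, verticalBand = c(0, 1),
                   minRoiPx = 1L)
    expect_equal(roiCoords(computeROI(px, p)), oracleROI(px, 50, c(0, 1)))
  }
})

test_that("ROI extraction precedes filtering in the pipeline contract", {
  # the ROI must be computed on raw intensities: a 1-px-wide bright border
  # column survives unfiltered detection but would be blurred away
  px <- matrix(0, 80, 80)
  px[20:60, 25] <- 255; px[20:60, 55] <- 255
  box <- computeROI(px, roiParams(intensityThreshold = 50,
                                  verticalBand = c(0, 1), minRoiPx = 1L))
  expect_equal(unname(roiCoords(box)[c("left", "right")]), c(24L, 55L))
  filt <- bilateralFilter(px / 255, filterParams(sigmaIntensity = 10))
  expect_lt(max(filt[, 25]), 0.5)  # heavy smoothing erases the line
})

test_that("bilateral filtering matches the double-loop oracle", {
  set.seed(5)
  img <- matrix(runif(30 * 25), 30, 25)
  p <- filterParams(sigmaSpatial = 2, sigmaIntensity = 0.15, radius = 2L)
  expect_equal(bilateralFilter(img, p),
               oracleBilateral(img, 2, 0.15, 2L), tolerance = 1e-12)
})

test_that("bilateral filtering preserves edges, ranges and constants", {
  const <- matrix(0.7, 20, 20)
  expect_equal(bilateralFilter(const), const, tolerance = 1e-12)

  step <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  out <- bilateralFilter(step)
  expect_true(all((out > 0.5) == (step > 0.5)))       # edge position kept
  far <- abs(out - step)[, c(1:7, 14:20)]             # >= 3 px from the edge
  expect_lt(max(far), 0.01)

  # impulse attenuated (wide intensity kernel so neighbours get weight)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  expect_lt(bilateralFilter(imp, filterParams(sigmaIntensity = 0.5))[11, 11],
            1)

  set.seed(8)
  img <- matrix(runif(40 * 40), 40, 40)
  out <- bilateralFilter(img)
  expect_gte(min(out), min(img))                      # convex combination
  expect_lte(max(out), max(img))

  expect_error(bilateralFilter(matrix(2, 10, 10)), "\\[0, 1\\]")
  expect_error(bilateralFilter(matrix(NaN, 10, 10)), "finite")
})

test_that("byte rescaling maps the range affinely with half-up rounding", {
  expect_identical(as.vector(rescaleToByte(matrix(c(0, 0.5, 1), 1))),
                   c(0L, 128L, 255L))
  expect_true(all(rescaleToByte(matrix(0.7, 5, 5)) == 0L))
  set.seed(4)
  m <- matrix(rnorm(200), 10, 20)
  r <- rescaleToByte(m)
  expect_equal(r[which.min(m)], 0L)
  expect_equal(r[which.max(m)], 255L)
  expect_true(all(diff(r[order(m)]) >= 0))            # order preserved
  # idempotent on full-range byte images
  b <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  b[1] <- 0L; b[2] <- 255L
  expect_identical(rescaleToByte(b), matrix(as.integer(b), 10, 10))
})
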