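test_that("thickness and width are calibrated pixel differences", {
  cal <- calibration(0.01, "config")
  u <- fakeDetection("a", 100); l <- fakeDetection("b", 220)
  expect_equal(thickness(u, l, cal), 1.20)
  expect_equal(thickness(u, u, cal), 0)
  expect_error(thickness(l, u, cal), "inverted")
  expect_error(thickness(u, fakeDetection("c", NA), cal), "missing")

  expect_equal(zoneWidth(ROIBox(30, 70, 0, 10), cal), 0.40)
  expect_equal(zoneWidth(ROIBox(0, 512, 0, 10), calibration()), 512)
  expect_equal(calibration()$units, "px")
})

test_that("rectangular area is the product", {
  expect_equal(rectArea(1.2, 0.4), 0.48)
  expect_equal(rectArea(0, 5), 0)
  set.seed(2)
  for (i in 1:20) {
    h <- runif(1, 0, 10); w <- runif(1, 0, 10)
    expect_identical(rectArea(h, w), h * w)
  }
})

test_that("the direct ellipse fit recovers exact parameters", {
  pts <- ellipsePoints(40, 50, 60, a = 30, b = 20, theta = 0.5)
  p <- fitEllipseDirect(pts)
  expect_equal(p$a, 30, tolerance = 1e-6)
  expect_equal(p$b, 20, tolerance = 1e-6)
  expect_equal(p$centerRow, 50, tolerance = 1e-6)
  expect_equal(p$centerCol, 60, tolerance = 1e-6)
  expect_equal(p$theta, 0.5, tolerance = 1e-6)
  # every input point satisfies the recovered ellipse equation
  u <- (pts[, 2] - p$centerCol) * cos(p$theta) +
       (pts[, 1] - p$centerRow) * sin(p$theta)
  v <- -(pts[, 2] - p$centerCol) * sin(p$theta) +
       (pts[, 1] - p$centerRow) * cos(p$theta)
  expect_lt(max(abs((u / p$a)^2 + (v / p$b)^2 - 1)), 1e-8)
})

test_that("circles and degenerate point sets behave correctly", {
  pts <- ellipsePoints(40, 5, -3, a = 10, b = 10, theta = 0)
  p <- fitEllipseDirect(pts)
  expect_equal(p$a, 10, tolerance = 1e-6)
  expect_equal(p$b, 10, tolerance = 1e-6)

  line <- cbind(1:6, 2 * (1:6) + 3)
  expect_error(fitEllipseDirect(line), "degenerate")
  expect_error(fitEllipseDirect(cbind(1:5, 1:5 * 2)), "at least 6")
})

test_that("the ellipse fit is invariant to rigid motion", {
  set.seed(17)
  base <- ellipsePoints(60, 0, 0, a = 14, b = 6, theta = 0)
  for (i in 1:10) {
    th <- runif(1, 0, pi); dr <- runif(1, -50, 50); dc <- runif(1, -50, 50)
    rot <- cbind(base[, 1] * cos(th) + base[, 2] * sin(th) + dr,
                 -base[, 1] * sin(th) + base[, 2] * cos(th) + dc)
    p <- fitEllipseDirect(rot)
    expect_equal(p$a, 14, tolerance = 1e-6)
    expect_equal(p$b, 6, tolerance = 1e-6)
  }
})

test_that("elliptical area follows the closed form and a Monte-Carlo oracle", {
  cal1 <- calibration(1, "config")
  expect_equal(ellipseArea(list(a = 3, b = 2), cal1), 6 * pi)
  expect_equal(ellipseArea(list(a = 1, b = 1), cal1), pi)
  # monotone in both semi-axes
  expect_gt(ellipseArea(list(a = 3.5, b = 2), cal1),
            ellipseArea(list(a = 3, b = 2), cal1))
  expect_gt(ellipseArea(list(a = 3, b = 2.5), cal1),
            ellipseArea(list(a = 3, b = 2), cal1))

  set.seed(19)
  a <- runif(1, 5, 20); b <- runif(1, 2, a)
  n <- 1e6
  x <- runif(n, -a, a); y <- runif(n, -b, b)
  mc <- mean((x / a)^2 + (y / b)^2 <= 1) * (2 * a) * (2 * b)
  expect_equal(ellipseArea(list(a = a, b = b), cal1), mc,
               tolerance = 0.01)
})

test_that("abdominal records carry the three fat thicknesses", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  roi <- ph$truth@roi
  roiImg <- cropROI(pixels(ph$scan), roi)
  dets <- validateOrder(detectStructures(roiImg, tl, descriptor(ph$scan)), tl)
  dets <- lapply(dets, function(d)
    refineContour(binarizeBbox(roiImg, bbox(d)), d))
  rec <- measureStructures(dets, roi, descriptor(ph$scan),
                           calibration(0.01, "config"), roiImg, "mini")
  tv <- ph$truth@values
  for (v in names(tv))
    expect_equal(rec@values[[v]], tv[[v]], tolerance = 0.051)
  expect_gte(rec@values[["Total Subcutaneous Fat"]],
             rec@values[["Superficial Subcutaneous Fat"]])
  expect_equal(length(rec@flags), 0L)
})

test_that("missing deep interfaces yield absent variables, never zeros", {
  dets <- list(fakeDetection("skin", 20),
               fakeDetection("fascia_superficial", 50),
               fakeDetection("muscle_wall", 80),
               fakeDetection("peritoneum", 100, flag = "detection_failure"),
               fakeDetection("peritoneal_deep", 130,
                             flag = "detection_failure"))
  rec <- measureStructures(dets, ROIBox(0, 100, 0, 160),
                           ScanDescriptor("abdomen", "transverse"),
                           calibration(0.01, "config"))
  expect_false("Peritoneal Fat" %in% names(rec@values))
  expect_equal(rec@values[["Total Subcutaneous Fat"]], 0.60)
  expect_match(paste(rec@flags, collapse = " "), "incomplete")
  expect_error(
    measureStructures(list(fakeDetection("skin", 10,
                                         flag = "detection_failure")),
                      ROIBox(0, 100, 0, 160),
                      ScanDescriptor("abdomen", "transverse")),
    "no valid detections")
})

test_that("lengths scale linearly and areas quadratically with calibration", {
  dets <- list(fakeDetection("skin", 10), fakeDetection("rectus_superficial", 40),
               fakeDetection("rectus_deep", 90), fakeDetection("vastus_deep", 130))
  roi <- ROIBox(0, 120, 0, 160)
  d <- ScanDescriptor("leg", "longitudinal")
  r1 <- measureStructures(dets, roi, d, calibration(0.01, "config"))
  r2 <- measureStructures(dets, roi, d, calibration(0.02, "config"))
  expect_equal(r2@values[["Y-axis Anterior Rectus"]],
               2 * r1@values[["Y-axis Anterior Rectus"]])
  expect_equal(r2@values[["X-axis Vastus Intermedius"]],
               2 * r1@values[["X-axis Vastus Intermedius"]])
  expect_equal(r2@values[["Anterior Rectus Area"]],
               4 * r1@values[["Anterior Rectus Area"]])
  expect_equal(r1@values[["Subcutaneous Fat"]], 0.30)  # leg-longitudinal extra
})
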