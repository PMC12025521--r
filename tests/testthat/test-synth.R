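test_that("phantom generation is deterministic in (spec, seed) and noise-only", {
  s1 <- miniSpec(speckleSigma = 0.25, seed = 5)
  p1 <- generatePhantom(s1)
  p2 <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = 5))
  expect_identical(pixels(p1$scan), pixels(p2$scan))

  p3 <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = 6))
  expect_false(identical(pixels(p1$scan), pixels(p3$scan)))
  expect_identical(p1$truth@values, p3$truth@values)
  expect_identical(p1$truth@boundaryRows, p3$truth@boundaryRows)
})

test_that("noiseless phantoms have the geometry their spec states", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  px <- pixels(ph$scan)
  tr <- ph$truth
  expect_equal(roiCoords(tr@roi),
               c(left = 10L, right = 110L, top = 10L, bottom = 150L))
  # black frame, bright bands exactly where declared
  expect_true(all(px[1:10, ] == 0) && all(px[, 1:10] == 0))
  expect_true(all(px[31:34, 60] == 210))       # skin band rows 30..33 0-based
  expect_equal(unname(tr@values["Superficial Subcutaneous Fat"]), 0.30)
  expect_equal(unname(tr@values["Total Subcutaneous Fat"]), 0.60)
  expect_equal(unname(tr@values["Peritoneal Fat"]), 0.25)
})

test_that("leg-transverse phantoms gain a fitted elliptical inclusion truth", {
  sp <- phantomSpec("leg", "transverse", speckleSigma = 0)
  expect_false(is.null(sp@inclusion))
  ph <- generatePhantom(sp)
  expect_equal(unname(ph$truth@values["Anterior Rectus Area"]),
               pi * sp@inclusion$a * sp@inclusion$b * sp@cmPerPx^2)
  # the inclusion lies strictly between the bounding aponeuroses
  b <- sp@boundaries
  expect_gt(sp@inclusion$centerRow - sp@inclusion$b,
            b$row[b$structure_id == "rectus_superficial"])
  expect_lt(sp@inclusion$centerRow + sp@inclusion$b,
            b$row[b$structure_id == "rectus_deep"])
})

test_that("invalid phantom geometry is rejected", {
  expect_error(miniSpecBad <- phantomSpec(
    "abdomen", "longitudinal", rows = 160L, cols = 120L, marginPx = 10L,
    boundaries = data.frame(structure_id = c("skin", "fascia_superficial"),
                            row = c(60, 30), brightness = 200, thickness = 4),
    zoneMeans = c(70, 50, 55)), "strictly increasing")
  expect_error(phantomSpec(
    "abdomen", "longitudinal", rows = 160L, cols = 120L, marginPx = 10L,
    boundaries = data.frame(structure_id = "skin", row = 148,
                            brightness = 200, thickness = 4),
    zoneMeans = c(70, 50)), "clearance")
})

test_that("speckled interface bands stay the brightest depth rows", {
  # premise of the centre-out ROI scan and of band-locked matching
  for (seed in 1:5) {
    ph <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = seed))
    px <- pixels(ph$scan)
    content <- px[11:150, 11:110]
    rowMean <- rowMeans(content)
    b <- miniSpec()@boundaries
    bandRows <- unlist(lapply(seq_len(nrow(b)), function(i)
      (b$row[i]:(b$row[i] + b$thickness[i] - 1)) - 10 + 1))
    expect_true(min(rowMean[bandRows]) > max(rowMean[-bandRows]))
  }
})

test_that("self-extracted templates score near unity on their phantom", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  expect_equal(length(tl), 5L)
  expect_equal(tl@manifest$order_index, 0:4)
  roiImg <- cropROI(pixels(ph$scan), ph$truth@roi)
  dets <- detectStructures(roiImg, tl, descriptor(ph$scan))
  expect_true(all(vapply(dets, matchScore, numeric(1)) >= 0.99))
  expect_error(extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 501L)),
               "placement")
})

test_that("template libraries generalize across phantom seeds", {
  libPh <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = 1))
  tl <- extractTemplates(libPh$scan, libPh$truth, patchSize = c(11L, 21L))
  for (seed in 2:4) {
    ph <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = seed))
    roiImg <- rescaleToByte(bilateralFilter(
      cropROI(pixels(ph$scan), ph$truth@roi) / 255))
    dets <- detectStructures(roiImg, tl, descriptor(ph$scan))
    found <- vapply(dets, interfaceRow, numeric(1)) + ph$truth@roi@top
    expect_true(all(abs(found - ph$truth@boundaryRows) <= 3))
  }
})

test_that("cohorts are reproducible, valid and jitter as asked", {
  base <- miniSpec(speckleSigma = 0.25)
  same <- generateCohort(5, base, depthPx = 0L, zoneMeanFrac = 0, seed = 3)
  truths <- lapply(same, function(x) x$truth@boundaryRows)
  for (t in truths) expect_identical(t, truths[[1]])
  imgs <- lapply(same, function(x) pixels(x$scan))
  expect_false(identical(imgs[[1]], imgs[[2]]))   # speckle still varies

  jit <- generateCohort(10, base, depthPx = 8L, seed = 4)
  rows <- t(vapply(jit, function(x) x$truth@boundaryRows, numeric(5)))
  expect_gt(nrow(unique(rows)), 1)
  for (x in jit) expect_true(validObject(x$spec))
  expect_true(all(abs(t(rows) - base@boundaries$row) <= 8))

  jit2 <- generateCohort(10, base, depthPx = 8L, seed = 4)
  expect_identical(pixels(jit[[7]]$scan), pixels(jit2[[7]]$scan))
})

test_that("a zero-noise reader agrees perfectly with the truth", {
  base <- miniSpec(speckleSigma = 0.25)
  co <- generateCohort(4, base, seed = 12)
  tf <- truthFrame(co)
  rd0 <- simulateReader(tf, sigma = 0, seed = 1)
  v <- "Total Subcutaneous Fat"
  expect_equal(precisionPercent(tf[[v]], rd0[[v]]), 100)
  rd <- simulateReader(tf, sigma = 0.05, seed = 1)
  expect_false(identical(tf[[v]], rd[[v]]))
})

test_that("cohorts export to a batch-ready directory", {
  base <- miniSpec(speckleSigma = 0.25)
  co <- generateCohort(3, base, seed = 8)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  pngs <- list.files(dir, pattern = "\\.png$")
  expect_equal(length(pngs), 3L)
  expect_true(all(grepl("_AB_L\\.png$", pngs)))
  tr <- utils::read.csv(file.path(dir, "truth.csv"), check.names = FALSE)
  expect_equal(nrow(tr), 3L)
  s <- readScan(file.path(dir, pngs[1]))
  expect_false(is.null(descriptor(s)))
  expect_identical(pixels(s), pixels(co[[1]]$scan) * 1)
})
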