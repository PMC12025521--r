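test_that("template matching scores a contained sub-window perfectly", {
  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  patch <- img[11:20, 21:35]
  res <- matchTemplate(img, patch)
  expect_equal(res@score, 1.0, tolerance = 1e-12)
  expect_equal(roiCoords(res@bbox),
               c(left = 20L, right = 35L, top = 10L, bottom = 20L))
})

test_that("a negated window anti-correlates at its own offset", {
  set.seed(22)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  patch <- 255 - img[6:13, 9:16]
  scores <- usquant:::.matchScores(img, patch, TRUE)
  expect_equal(scores[6, 9], -1.0, tolerance = 1e-12)
})

test_that("matching equals the exhaustive correlation oracle on random pairs", {
  set.seed(23)
  for (i in 1:10) {
    img <- matrix(runif(48 * 52, 0, 255), 48, 52)
    patch <- matrix(runif(9 * 9, 0, 255), 9, 9)
    scores <- usquant:::.matchScores(img, patch, TRUE)
    oracle <- oracleMatchScores(img, patch)
    expect_equal(scores, oracle, tolerance = 1e-9)
    res <- matchTemplate(img, patch)
    expect_equal(which.max(scores), which.max(oracle))
    expect_equal(res@score, max(oracle), tolerance = 1e-9)
  }
})

test_that("degenerate matching inputs error out", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_error(matchTemplate(img, img), "strictly smaller")
  expect_error(matchTemplate(img, matrix(7, 3, 3)), "zero variance")
})

test_that("raw correlation is available and brightness-biased as expected", {
  img <- matrix(10, 30, 30); img[20:28, 20:28] <- 250
  patch <- matrix(c(100, 120, 110, 130), 2, 2)
  res <- matchTemplate(img, patch, method = "ccorr")
  expect_gte(res@bbox@top, 19L)   # locks onto the brightest window
  expect_gte(res@bbox@left, 19L)
})

test_that("variant generation is ordered, deterministic and size-guarded", {
  set.seed(31)
  patch <- matrix(runif(100, 0, 255), 10, 10)
  v <- generateVariants(patch, matchConfig(variantScales = c(0.9, 1.1),
                                           variantContrasts = c(0.8, 1.2)))
  expect_equal(length(v), 5L)
  expect_identical(v[[1]], patch)
  expect_equal(dim(v[[2]]), c(9L, 9L))
  expect_equal(dim(v[[3]]), c(11L, 11L))
  expect_true(all(vapply(v, function(x) all(x >= 0 & x <= 255), logical(1))))

  v1 <- generateVariants(patch, matchConfig(variantScales = 1.0,
                                            variantContrasts = numeric(0)))
  expect_equal(length(v1), 1L)

  vc <- generateVariants(patch, matchConfig(variantScales = numeric(0),
                                            variantContrasts = 1.0))
  expect_identical(vc[[2]], patch)  # contrast 1 is the identity map

  expect_message(
    generateVariants(matrix(runif(16, 0, 255), 4, 4),
                     matchConfig(variantScales = 0.5,
                                 variantContrasts = numeric(0))),
    "below 3x3")
})

test_that("self-extracted templates recover noiseless phantom interfaces exactly", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  roi <- ph$truth@roi
  roiImg <- cropROI(pixels(ph$scan), roi)
  dets <- detectStructures(roiImg, tl, descriptor(ph$scan))
  expect_equal(length(dets), 5L)
  expect_true(all(vapply(dets, detectionFlag, character(1)) == ""))
  found <- vapply(dets, interfaceRow, numeric(1)) + roi@top
  expect_true(all(abs(found - ph$truth@boundaryRows) <= 1))
  expect_true(all(vapply(dets, matchScore, numeric(1)) >= 0.99))
})

test_that("ordered fallback uses later variants when earlier ones fail", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  roiImg <- cropROI(pixels(ph$scan), ph$truth@roi)
  cfg <- matchConfig()
  # first variant degenerate (flat), second is the true patch
  variants <- list(flat = matrix(100, 11, 21), original = tl@patches[[1]])
  m <- usquant:::.matchInBand(roiImg, variants, cfg, "skin",
                              direction = "down")
  expect_false(is.null(m))
  expect_equal(m$match@variantIndex, 1L)
  expect_gte(m$match@score, 0.99)
})

test_that("uncorrelated noise yields flagged detection failures, not crashes", {
  set.seed(41)
  noise <- matrix(runif(140 * 100, 0, 255), 140, 100)
  ph <- generatePhantom(miniSpec(speckleSigma = 0))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  dets <- detectStructures(noise, tl, ScanDescriptor("abdomen", "longitudinal"),
                           matchConfig(acceptScore = 0.95))
  expect_true(all(vapply(dets, detectionFlag, character(1)) ==
                    "detection_failure"))
  expect_true(all(is.na(vapply(dets, matchScore, numeric(1)))))
})

test_that("detection is byte-deterministic on identical inputs", {
  ph <- generatePhantom(miniSpec(speckleSigma = 0.25, seed = 77))
  tl <- extractTemplates(ph$scan, ph$truth, patchSize = c(11L, 21L))
  roiImg <- rescaleToByte(bilateralFilter(
    cropROI(pixels(ph$scan), ph$truth@roi) / 255))
  d1 <- detectStructures(roiImg, tl, descriptor(ph$scan))
  d2 <- detectStructures(roiImg, tl, descriptor(ph$scan))
  expect_identical(lapply(d1, function(d) list(structureId(d), matchScore(d),
                                               roiCoords(bbox(d)))),
                   lapply(d2, function(d) list(structureId(d), matchScore(d),
                                               roiCoords(bbox(d)))))
})

test_that("order validation passes monotone stacks and demotes violators", {
  ok <- list(fakeDetection("skin", 10), fakeDetection("fascia_superficial", 40),
             fakeDetection("muscle_wall", 90))
  out <- validateOrder(ok)
  expect_true(all(vapply(out, detectionFlag, character(1)) == ""))

  bad <- list(fakeDetection("skin", 50, score = 0.95),
              fakeDetection("fascia_superficial", 20, score = 0.8))
  out <- validateOrder(bad)
  expect_equal(detectionFlag(out[[1]]), "")
  expect_equal(detectionFlag(out[[2]]), "order_violation")

  # deep overlap beyond half the smaller box demotes the weaker match
  ovl <- list(fakeDetection("skin", 30, top = 25, bottom = 40, score = 0.7),
              fakeDetection("fascia_superficial", 33, top = 26, bottom = 41,
                            score = 0.9))
  out <- validateOrder(ovl)
  expect_equal(detectionFlag(out[[1]]), "order_violation")
  expect_equal(detectionFlag(out[[2]]), "")
})

test_that("validated detections are always monotone in depth", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    dets <- lapply(seq_len(n), function(k)
      fakeDetection(paste0("s", k), row = sample(5:140, 1),
                    score = runif(1, 0.5, 1)))
    out <- validateOrder(dets)
    keep <- Filter(function(d) detectionFlag(d) == "", out)
    rows <- vapply(keep, interfaceRow, numeric(1))
    expect_true(!is.unsorted(rows, strictly = TRUE))
  }
})

test_that("contour refinement is exact on clean rectangles and robust to salt", {
  mask <- matrix(FALSE, 60, 60)
  mask[21:40, 16:45] <- TRUE
  det <- fakeDetection("skin", 30, top = 5, bottom = 45, left = 10,
                       right = 50)
  out <- refineContour(mask, det, kernelRadius = 2L)
  expect_equal(interfaceRow(out), 20)          # top row, 0-based
  expect_equal(detectionFlag(out), "")
  expect_true(all(contour(out)[, "row"] >= 20 & contour(out)[, "row"] <= 39))

  salted <- mask
  set.seed(61)
  specks <- cbind(sample(7:9, 6, TRUE), sample(11:49, 6, TRUE))
  salted[specks] <- TRUE           # 1-px salt well above the slab
  out2 <- refineContour(salted, det, kernelRadius = 2L)
  expect_equal(interfaceRow(out2), interfaceRow(out))
  expect_equal(sort(unique(contour(out2)[, "row"])),
               sort(unique(contour(out)[, "row"])))
})

test_that("an empty mask falls back to the bbox outline with a flag", {
  det <- fakeDetection("skin", 30, top = 5, bottom = 45, left = 10,
                       right = 50)
  out <- refineContour(matrix(FALSE, 60, 60), det, kernelRadius = 2L)
  expect_equal(detectionFlag(out), "refine_fallback")
  expect_equal(interfaceRow(out), 30)           # provisional row kept
  expect_true(nrow(contour(out)) > 0)
})
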