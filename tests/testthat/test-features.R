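test_that("the 2x2 checker window gives the hand-enumerated GLCM and features", {
  win <- matrix(c(0, 0, 255, 255), 2, 2)   # columns [0,0] and [255,255]
  g <- glcm(win, glcmSpec(levels = 2, angles = 0))
  P <- g[[1]]
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1] + P[2, 2], 0)

  f <- textureFeatures(g)
  expect_equal(unname(f["asm"]), 0.5)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)          # 1 bit
  expect_equal(unname(f["correlation"]), -1)
})

test_that("constant windows are the degenerate single-cell distribution", {
  g <- glcm(matrix(40, 8, 8), glcmSpec(levels = 16))
  for (P in g) {
    expect_equal(sum(P), 1)
    expect_equal(P[3, 3], 1)                     # level floor(40*16/256)=2
  }
  f <- textureFeatures(g)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["dissimilarity"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["correlation"]), 0)      # zero-variance convention
})

test_that("GLCMs and features match the pair-enumeration oracle", {
  set.seed(101)
  spec <- glcmSpec()
  for (i in 1:10) {
    win <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    g <- glcm(win, spec)
    for (k in seq_along(spec$angles))
      expect_equal(g[[k]], oracleGLCM(win, spec$levels, spec$angles[k]),
                   tolerance = 1e-14)
    f <- textureFeatures(g)
    oracle <- rowMeans(vapply(g, oracleTextureFeatures, numeric(6)))
    expect_equal(f, oracle, tolerance = 1e-10)
  }
})

test_that("GLCM input contracts are enforced", {
  expect_error(glcm(matrix(0, 1, 5)), "2")
  expect_error(glcm(matrix(0, 2, 2), glcmSpec(distancePx = 3)), "pairs")
  bad <- list(matrix(0.3, 4, 4))
  expect_error(textureFeatures(bad), "not normalized")
})

test_that("the histogram mean equals the pixel mean", {
  expect_equal(histogramMean(matrix(17, 6, 6)), 17)
  expect_equal(histogramMean(matrix(c(0, 255), 4, 4)), 127.5)
  set.seed(13)
  win <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  expect_equal(histogramMean(win), mean(win), tolerance = 1e-12)
})

test_that("texture features are transpose-invariant under the symmetric default", {
  set.seed(14)
  win <- matrix(sample(0:255, 15 * 21, replace = TRUE), 15, 21)
  f1 <- textureVariables(win)
  f2 <- textureVariables(t(win))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("entropy vanishes exactly when ASM is 1, and noise moves both", {
  set.seed(15)
  for (i in 1:10) {
    win <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    f <- textureFeatures(glcm(win))
    expect_equal(unname(f["entropy"]) == 0, unname(f["asm"]) == 1)
  }
  const <- matrix(100, 16, 16)
  f0 <- textureFeatures(glcm(const))
  for (s in 1:8) {
    set.seed(400 + s)
    noisy <- const + matrix(sample(0:100, 256, replace = TRUE), 16, 16)
    f1 <- textureFeatures(glcm(noisy))
    expect_lt(unname(f1["asm"]), unname(f0["asm"]))
    expect_gt(unname(f1["entropy"]), unname(f0["entropy"]))
  }
})

test_that("identical windows give bit-identical feature vectors", {
  set.seed(16)
  win <- matrix(sample(0:255, 600, replace = TRUE), 20, 30)
  expect_identical(textureVariables(win), textureVariables(win))
})

test_that("the inverse-difference homogeneity dialect is available", {
  set.seed(18)
  win <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  g <- glcm(win, glcmSpec(levels = 8))
  idm <- textureFeatures(g)[["homogeneity"]]
  id <- textureFeatures(g, homogeneityForm = "id")[["homogeneity"]]
  expect_false(isTRUE(all.equal(idm, id)))
  P <- g[[1]]; L <- nrow(P)
  manual <- 0
  for (i in 1:L) for (j in 1:L) manual <- manual + P[i, j] / (1 + abs(i - j))
  expect_equal(textureFeatures(g[1], homogeneityForm = "id")[["homogeneity"]],
               manual, tolerance = 1e-12)
})
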