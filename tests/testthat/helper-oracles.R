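# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: scalar loops and textbook definitions
# only.

# full-scan ROI oracle: outermost supra-threshold columns (band-restricted)
# and rows; valid for fixtures whose bright region straddles the image centre
oracleROI <- function(px, thr, band = c(0.25, 0.75)) {
  h <- nrow(px); w <- ncol(px)
  bandRows <- max(1, floor(band[1] * h) + 1):min(h, ceiling(band[2] * h))
  colOk <- logical(w)
  for (cc in seq_len(w))
    for (r in bandRows) if (px[r, cc] > thr) { colOk[cc] <- TRUE; break }
  if (!any(colOk)) return(NULL)
  left <- min(which(colOk)); right <- max(which(colOk))
  rowOk <- logical(h)
  for (r in seq_len(h))
    for (cc in left:right) if (px[r, cc] > thr) { rowOk[r] <- TRUE; break }
  if (!any(rowOk)) return(NULL)
  c(left = left - 1L, right = right, top = min(which(rowOk)) - 1L,
    bottom = max(which(rowOk)))
}

# exhaustive all-offset normalized correlation oracle
oracleMatchScores <- function(img, patch) {
  pr <- nrow(patch); pc <- ncol(patch)
  orows <- nrow(img) - pr + 1; ocols <- ncol(img) - pc + 1
  out <- matrix(NA_real_, orows, ocols)
  pv <- as.vector(patch)
  for (i in seq_len(orows))
    for (j in seq_len(ocols)) {
      wv <- as.vector(img[i:(i + pr - 1), j:(j + pc - 1)])
      out[i, j] <- if (stats::sd(wv) == 0) 0 else stats::cor(wv, pv)
    }
  out
}

# scalar-loop bilateral filter oracle on [0, 1] intensities
oracleBilateral <- function(img, sigmaSpatial, sigmaIntensity, radius) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0; wacc <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      wt <- exp(-(di^2 + dj^2) / (2 * sigmaSpatial^2)) *
            exp(-(img[ii, jj] - img[i, j])^2 / (2 * sigmaIntensity^2))
      acc <- acc + wt * img[ii, jj]; wacc <- wacc + wt
    }
    out[i, j] <- acc / wacc
  }
  out
}

# pair-enumeration GLCM oracle (0-based levels), equal-width quantization
oracleGLCM <- function(window, levels, angle, d = 1, symmetric = TRUE) {
  q <- floor(pmin(pmax(window, 0), 255) * levels / 256)
  dr <- -round(d * sin(angle)); dc <- round(d * cos(angle))
  P <- matrix(0, levels, levels)
  h <- nrow(q); w <- ncol(q)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- i + dr; jj <- j + dc
    if (ii < 1 || ii > h || jj < 1 || jj > w) next
    P[q[i, j] + 1, q[ii, jj] + 1] <- P[q[i, j] + 1, q[ii, jj] + 1] + 1
  }
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

# textbook summation oracle for the six co-occurrence features
oracleTextureFeatures <- function(P) {
  L <- nrow(P)
  asm <- 0; contrast <- 0; dissim <- 0; homog <- 0; entropy <- 0
  mi <- 0; mj <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    mi <- mi + (i - 1) * p; mj <- mj + (j - 1) * p
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    homog <- homog + p / (1 + (i - j)^2)
    if (p > 0) entropy <- entropy - p * log2(p)
    vi <- vi + (i - 1 - mi)^2 * p
    vj <- vj + (j - 1 - mj)^2 * p
    cov <- cov + (i - 1 - mi) * (j - 1 - mj) * p
  }
  corr <- if (vi * vj == 0) 0 else cov / sqrt(vi * vj)
  c(asm = asm, contrast = contrast, correlation = corr,
    dissimilarity = dissim, entropy = entropy, homogeneity = homog)
}

# exact points on an ellipse in (row, col) coordinates
ellipsePoints <- function(n, centerRow, centerCol, a, b, theta,
                          noiseSd = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * cos(t); v <- b * sin(t)
  col <- centerCol + u * cos(theta) - v * sin(theta)
  row <- centerRow + u * sin(theta) + v * cos(theta)
  if (noiseSd > 0) {
    row <- row + rnorm(n, 0, noiseSd)
    col <- col + rnorm(n, 0, noiseSd)
  }
  cbind(row, col)
}
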