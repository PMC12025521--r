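#' @include AllClasses.R
NULL

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between an automatic and a manual (reference)
#' measurement series: differences `d = auto - manual`, bias `mean(d)`,
#' 95% limits of agreement `bias -/+ 1.96 * sd(d)` (sample SD), and the
#' 95% confidence interval of the bias `bias -/+ 1.96 * sd(d) / sqrt(n)`.
#' The per-pair `((auto + manual) / 2, d)` points are retained as the plot
#' data.
#'
#' @param auto,manual equal-length numeric vectors, `n >= 2`, finite.
#' @param variable name recorded in the result.
#' @return An [AgreementResult-class].
#' @examples
#' blandAltman(c(2, 4), c(1, 3))  # bias 1, LoA [1, 1]
#' @export
blandAltman <- function(auto, manual, variable = "") {
  stopifnot(is.numeric(auto), is.numeric(manual))
  if (length(auto) != length(manual))
    stop("auto and manual series must have equal length")
  if (length(auto) < 2L)
    stop("Bland-Altman analysis needs at least 2 pairs")
  if (!all(is.finite(auto)) || !all(is.finite(manual)))
    stop("non-finite measurement values")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  AgreementResult(variable = as.character(variable), bias = bias,
                  loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
                  ciBias = c(bias - 1.96 * s / sqrt(n),
                             bias + 1.96 * s / sqrt(n)),
                  n = as.integer(n),
                  points = data.frame(mean = (auto + manual) / 2,
                                      difference = d))
}

#' Precision of automatic measurements against a manual reference
#'
#' `precision = 100 - MAPE`, where MAPE is the mean absolute percentage
#' error `(100 / n) * sum(|auto - manual| / |manual|)`, clipped below at 0.
#' The score is scale-invariant: rescaling both series by a common positive
#' factor leaves it unchanged. An optional bootstrap yields a 95%
#' percentile confidence interval.
#'
#' @param auto,manual equal-length numeric vectors; `manual` must be
#'   nonzero everywhere (the reference defines the percentage scale).
#' @param ci if `TRUE`, attach a bootstrap 95% CI as attribute `"ci95"`.
#' @param nboot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap resampling (default 1).
#' @return Precision in percent (a single number).
#' @examples
#' precisionPercent(110, 100)  # 90
#' @export
precisionPercent <- function(auto, manual, ci = FALSE, nboot = 2000L,
                             seed = 1L) {
  stopifnot(is.numeric(auto), is.numeric(manual))
  if (length(auto) != length(manual))
    stop("auto and manual series must have equal length")
  if (length(auto) < 1L) stop("precision needs at least one pair")
  if (any(manual == 0))
    stop("undefined reference: manual values must be nonzero")
  ape <- abs(auto - manual) / abs(manual)
  prec <- function(x) max(0, 100 - 100 * mean(x))
  out <- prec(ape)
  if (ci) {
    n <- length(ape)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    reps <- vapply(seq_len(nboot), function(i)
      prec(ape[sample.int(n, n, replace = TRUE)]), numeric(1))
    attr(out, "ci95") <- unname(stats::quantile(reps, c(0.025, 0.975)))
  }
  out
}
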