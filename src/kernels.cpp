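#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window template scores over every valid offset.
// normalized = true: zero-mean normalized cross-correlation (Pearson on the
// window/patch pair); a zero-variance window scores 0 by convention.
// normalized = false: raw cross-correlation sum(W * T) (the TM_CCORR flavour).
// [[Rcpp::export(name = ".matchScores")]]
NumericMatrix match_scores(NumericMatrix image, NumericMatrix patch,
                           bool normalized) {
  const int ir = image.nrow(), ic = image.ncol();
  const int pr = patch.nrow(), pc = patch.ncol();
  const int orows = ir - pr + 1, ocols = ic - pc + 1;
  if (orows < 1 || ocols < 1)
    stop("patch must be strictly smaller than the image");
  const int n = pr * pc;

  double tsum = 0.0, tsq = 0.0;
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) {
      const double v = patch(i, j);
      tsum += v;
      tsq += v * v;
    }
  const double tmean = tsum / n;
  const double tvar = tsq - tsum * tsum / n;  // sum of squared deviations

  NumericMatrix out(orows, ocols);
  for (int oc = 0; oc < ocols; ++oc) {
    for (int orr = 0; orr < orows; ++orr) {
      double wsum = 0.0, wsq = 0.0, cross = 0.0;
      for (int j = 0; j < pc; ++j) {
        for (int i = 0; i < pr; ++i) {
          const double w = image(orr + i, oc + j);
          wsum += w;
          wsq += w * w;
          cross += w * patch(i, j);
        }
      }
      if (!normalized) {
        out(orr, oc) = cross;
      } else {
        const double wvar = wsq - wsum * wsum / n;
        const double num = cross - wsum * tmean;
        const double den = std::sqrt(wvar * tvar);
        out(orr, oc) = (den > 0.0) ? num / den : 0.0;
      }
    }
  }
  return out;
}

// Brute-force bilateral filter on intensities in [0, 1]. Neighbours outside
// the image are excluded (weights renormalize); no padding is used.
// [[Rcpp::export(name = ".bilateralCpp")]]
NumericMatrix bilateral_cpp(NumericMatrix image, double sigma_spatial,
                            double sigma_intensity, int radius) {
  const int nr = image.nrow(), nc = image.ncol();
  const double s2 = 2.0 * sigma_spatial * sigma_spatial;
  const double r2 = 2.0 * sigma_intensity * sigma_intensity;
  NumericMatrix out(nr, nc);

  // spatial weights are shift-invariant: precompute the (2r+1)^2 stencil
  const int w = 2 * radius + 1;
  std::vector<double> gs(w * w);
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      gs[(dj + radius) * w + (di + radius)] =
          std::exp(-(double)(di * di + dj * dj) / s2);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double center = image(i, j);
      double acc = 0.0, wacc = 0.0;
      const int ilo = std::max(0, i - radius), ihi = std::min(nr - 1, i + radius);
      const int jlo = std::max(0, j - radius), jhi = std::min(nc - 1, j + radius);
      for (int jj = jlo; jj <= jhi; ++jj) {
        for (int ii = ilo; ii <= ihi; ++ii) {
          const double v = image(ii, jj);
          const double d = v - center;
          const double wt = gs[(jj - j + radius) * w + (ii - i + radius)] *
                            std::exp(-d * d / r2);
          acc += wt * v;
          wacc += wt;
        }
      }
      out(i, j) = acc / wacc;
    }
  }
  return out;
}
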