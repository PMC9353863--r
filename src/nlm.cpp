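#include <Rcpp.h>
using namespace Rcpp;

// Non-local means denoising with either the classical exponential patch
// weight or the cosine-windowed variant with a hard cutoff.
//
// Patch distances are Gaussian-weighted mean squared differences over a
// (2p+1)^2 patch; the Gaussian kernel is normalised to sum 1. Patches are
// taken from a mirror-padded copy of the image so every pixel has a full
// patch; the search window is clipped to the image domain. The self-weight
// is replaced by the maximum weight seen among the other candidates, the
// usual convention preventing the noisy centre pixel from dominating.
//
// scheme: 0 = classical exp(-D/h^2), 1 = improved
//         exp(-D/h1^2) * cos(pi*D/(2*h2)) for D <= h2, else 0.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, int patch_r, int search_r,
                              double kernel_sd, double h, double h1,
                              double h2, int scheme) {
  const int nr = img.nrow(), nc = img.ncol();
  const int p = patch_r, s = search_r;
  const int side = 2 * p + 1;

  // mirror-padded image (half-sample symmetric)
  const int nrp = nr + 2 * p, ncp = nc + 2 * p;
  NumericMatrix pad(nrp, ncp);
  for (int i = 0; i < nrp; ++i) {
    int ii = i - p;
    if (ii < 0) ii = -ii - 1;
    if (ii >= nr) ii = 2 * nr - ii - 1;
    for (int j = 0; j < ncp; ++j) {
      int jj = j - p;
      if (jj < 0) jj = -jj - 1;
      if (jj >= nc) jj = 2 * nc - jj - 1;
      pad(i, j) = img(ii, jj);
    }
  }

  // normalised Gaussian patch kernel
  NumericMatrix g(side, side);
  double gsum = 0.0;
  for (int a = -p; a <= p; ++a)
    for (int b = -p; b <= p; ++b) {
      double w = std::exp(-(a * a + b * b) / (2.0 * kernel_sd * kernel_sd));
      g(a + p, b + p) = w;
      gsum += w;
    }
  for (int a = 0; a < side; ++a)
    for (int b = 0; b < side; ++b) g(a, b) /= gsum;

  NumericMatrix out(nr, nc);
  const double h_sq = h * h, h1_sq = h1 * h1;

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const int r0 = std::max(0, i - s), r1 = std::min(nr - 1, i + s);
      const int c0 = std::max(0, j - s), c1 = std::min(nc - 1, j + s);
      double wsum = 0.0, vsum = 0.0, wmax = 0.0;
      for (int r = r0; r <= r1; ++r) {
        for (int c = c0; c <= c1; ++c) {
          if (r == i && c == j) continue;
          double d = 0.0;
          for (int a = -p; a <= p; ++a)
            for (int b = -p; b <= p; ++b) {
              double diff = pad(i + p + a, j + p + b) - pad(r + p + a, c + p + b);
              d += g(a + p, b + p) * diff * diff;
            }
          double w;
          if (scheme == 0) {
            w = std::exp(-d / h_sq);
          } else {
            w = (d <= h2)
              ? std::exp(-d / h1_sq) * std::cos(M_PI * d / (2.0 * h2))
              : 0.0;
          }
          if (w > wmax) wmax = w;
          wsum += w;
          vsum += w * img(r, c);
        }
      }
      // self-weight = max of the others (1 if the window was empty of mass)
      double wself = (wmax > 0.0) ? wmax : 1.0;
      wsum += wself;
      vsum += wself * img(i, j);
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
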