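#include <Rcpp.h>
using namespace Rcpp;

// Smoothed wavelet coherence from two CWT coefficient matrices.
//
// Wx, Wy: complex matrices, time in rows, scales in columns (same shape).
// hw:     per-column smoothing half-width in samples; the smoothing operator
//         is an edge-normalized boxcar running mean along time.
// Returns |<Wx Wy*>| / sqrt(<|Wx|^2><|Wy|^2>), clipped to [0, 1]; columns
// whose auto spectra vanish (silent channel) yield 0.
// [[Rcpp::export(name = ".coh_kernel")]]
NumericMatrix coh_kernel(ComplexMatrix Wx, ComplexMatrix Wy,
                         IntegerVector hw) {
  const int nt = Wx.nrow(), nf = Wx.ncol();
  if (Wy.nrow() != nt || Wy.ncol() != nf)
    stop("coh_kernel: shape mismatch");
  if (hw.size() != nf)
    stop("coh_kernel: one half-width per scale required");
  NumericMatrix coh(nt, nf);
  std::vector<double> cxx(nt + 1), cyy(nt + 1), cre(nt + 1), cim(nt + 1);
  const double tiny = 1e-300;
  const Rcomplex *px = Wx.begin(), *py = Wy.begin();
  for (int j = 0; j < nf; ++j) {
    const Rcomplex *wxc = px + (size_t)j * nt;
    const Rcomplex *wyc = py + (size_t)j * nt;
    cxx[0] = cyy[0] = cre[0] = cim[0] = 0.0;
    for (int i = 0; i < nt; ++i) {
      const double xr = wxc[i].r, xi = wxc[i].i;
      const double yr = wyc[i].r, yi = wyc[i].i;
      cxx[i + 1] = cxx[i] + xr * xr + xi * xi;
      cyy[i + 1] = cyy[i] + yr * yr + yi * yi;
      cre[i + 1] = cre[i] + xr * yr + xi * yi;   // Re(Wx * conj(Wy))
      cim[i + 1] = cim[i] + xi * yr - xr * yi;   // Im(Wx * conj(Wy))
    }
    const int h = hw[j];
    double *out = coh.begin() + (size_t)j * nt;
    for (int i = 0; i < nt; ++i) {
      const int lo = std::max(i - h, 0);
      const int hi = std::min(i + h + 1, nt);
      const double sxx = cxx[hi] - cxx[lo];
      const double syy = cyy[hi] - cyy[lo];
      const double sre = cre[hi] - cre[lo];
      const double sim = cim[hi] - cim[lo];
      const double den = sxx * syy;
      double c = den > tiny ? std::sqrt((sre * sre + sim * sim) / den) : 0.0;
      if (c > 1.0) c = 1.0;
      out[i] = c;
    }
  }
  return coh;
}

// Edge-normalized boxcar running mean along time, one half-width per column.
// [[Rcpp::export(name = ".smooth_columns")]]
NumericMatrix smooth_columns(NumericMatrix M, IntegerVector hw) {
  const int nt = M.nrow(), nf = M.ncol();
  if (hw.size() != nf) stop("smooth_columns: one half-width per column");
  NumericMatrix out(nt, nf);
  std::vector<double> cs(nt + 1);
  for (int j = 0; j < nf; ++j) {
    cs[0] = 0.0;
    for (int i = 0; i < nt; ++i) cs[i + 1] = cs[i] + M(i, j);
    const int h = hw[j];
    for (int i = 0; i < nt; ++i) {
      const int lo = std::max(i - h, 0);
      const int hi = std::min(i + h + 1, nt);
      out(i, j) = (cs[hi] - cs[lo]) / (hi - lo);
    }
  }
  return out;
}
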