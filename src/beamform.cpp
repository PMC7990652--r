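#include <RcppArmadillo.h>
using namespace Rcpp;

// Dynamic-receive-focus delay stack on complex baseband channel data.
//
// For pixel (depth z, line x_l) and element e the receive path delay is
// t = z/c + dist(pixel, element)/c. The baseband sample at t is looked
// up with linear interpolation and phase-rotated by exp(+i 2 pi f_d t)
// to undo the demodulation phase at the true delay. No apodization.
// Out-of-record times contribute zero.
//
// Returns a complex array (n_depth x n_lines x n_elem); summing over
// the third dimension gives the DAS image.
// [[Rcpp::export]]
ComplexVector cpp_focused_stack(ComplexMatrix baseband, double fs,
                                double t_start, double f_demod, double c,
                                NumericVector elem_x,
                                NumericVector line_x,
                                NumericVector depth_z) {
  const int n_time = baseband.nrow();
  const int n_elem = baseband.ncol();
  const int nd = depth_z.size();
  const int nl = line_x.size();

  ComplexVector out((R_xlen_t)nd * nl * n_elem);
  out.attr("dim") = IntegerVector::create(nd, nl, n_elem);

  const double two_pi_fd = 2.0 * M_PI * f_demod;

  for (int e = 0; e < n_elem; ++e) {
    const Rcomplex *ch = &baseband(0, e);
    const double xe = elem_x[e];
    for (int l = 0; l < nl; ++l) {
      const double dxl = line_x[l] - xe;
      for (int d = 0; d < nd; ++d) {
        const double z = depth_z[d];
        const double dist = std::sqrt(dxl * dxl + z * z);
        const double t = z / c + dist / c;
        const double u = (t - t_start) * fs;
        Rcomplex val;
        val.r = 0.0; val.i = 0.0;
        const int iu = (int)std::floor(u);
        if (iu >= 0 && iu < n_time - 1) {
          const double frac = u - iu;
          const double re = ch[iu].r + frac * (ch[iu + 1].r - ch[iu].r);
          const double im = ch[iu].i + frac * (ch[iu + 1].i - ch[iu].i);
          const double ph = two_pi_fd * t;
          const double cp = std::cos(ph), sp = std::sin(ph);
          val.r = re * cp - im * sp;
          val.i = re * sp + im * cp;
        }
        out[(R_xlen_t)d + (R_xlen_t)nd * l + (R_xlen_t)nd * nl * e] = val;
      }
    }
  }
  return out;
}
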