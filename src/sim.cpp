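#include <RcppArmadillo.h>
using namespace Rcpp;

// Plane-wave insonification of a point-scatterer field.
//
// Each receive channel is the superposition over scatterers of a
// Gaussian-windowed sinusoid arriving at t = z_s/c + dist(s, e)/c
// (0-degree plane-wave transmit + element receive path), scaled by the
// scatterer reflectivity, 1/dist geometric spreading, and two-way
// frequency-independent attenuation evaluated at the transmit
// frequency.
//
// Implementation: per channel, scatterer arrivals are accumulated as
// linearly-interpolated impulses on a time grid oversampled by `os`
// relative to fs (the triangular interpolation kernel's sinc^2 rolloff
// at the pulse band is < 0.5 % for os = 4); the impulse train is then
// convolved with the sampled pulse via FFT and decimated back to fs.
//
// Units: positions in metres, times in seconds, attenuation in
// dB/(cm*MHz).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_plane_wave(NumericVector scat_x,
                                      NumericVector scat_z,
                                      NumericVector scat_amp,
                                      NumericVector elem_x,
                                      double c, double fs, double f_tx,
                                      double sigma_t, double half_width,
                                      double atten_db_cm_mhz,
                                      double t_start, int n_time,
                                      int os = 4) {
  const int n_scat = scat_x.size();
  const int n_elem = elem_x.size();
  const double fso = fs * os;
  const double dt_os = 1.0 / fso;
  const int n_os = n_time * os;

  // pulse sampled on the oversampled grid, centred at index c0
  const int hw_n = (int)std::ceil(half_width * fso);
  const int npul = 2 * hw_n + 1;
  arma::vec pulse(npul);
  const double two_pi_f = 2.0 * M_PI * f_tx;
  for (int i = 0; i < npul; ++i) {
    const double t = (i - hw_n) * dt_os;
    pulse(i) = std::exp(-t * t / (2.0 * sigma_t * sigma_t)) *
               std::cos(two_pi_f * t);
  }

  int nfft = 1;
  while (nfft < n_os + npul) nfft <<= 1;
  arma::cx_vec P = arma::fft(pulse, nfft);

  const double f_mhz = f_tx * 1e-6;
  const double ln10_20 = std::log(10.0) / 20.0;

  NumericMatrix out(n_time, n_elem);
  arma::vec train(n_os);
  for (int e = 0; e < n_elem; ++e) {
    train.zeros();
    const double xe = elem_x[e];
    for (int s = 0; s < n_scat; ++s) {
      const double a0 = scat_amp[s];
      if (a0 == 0.0) continue;
      const double dx = scat_x[s] - xe;
      const double zs = scat_z[s];
      const double dist = std::sqrt(dx * dx + zs * zs);
      const double t_arr = zs / c + dist / c;
      double amp = a0 / dist;
      if (atten_db_cm_mhz > 0.0) {
        const double path_cm = (zs + dist) * 100.0;
        amp *= std::exp(-atten_db_cm_mhz * f_mhz * path_cm * ln10_20);
      }
      const double u = (t_arr - t_start) * fso;
      const int iu = (int)std::floor(u);
      if (iu < 0 || iu >= n_os - 1) continue;
      const double frac = u - iu;
      train(iu) += amp * (1.0 - frac);
      train(iu + 1) += amp * frac;
    }
    arma::cx_vec Y = arma::ifft(arma::fft(train, nfft) % P, nfft);
    // convolution index of output sample k (at fs): k*os + hw_n
    double *col = &out(0, e);
    for (int k = 0; k < n_time; ++k)
      col[k] = Y((size_t)k * os + hw_n).real();
  }
  return out;
}
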