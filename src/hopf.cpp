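#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integration of M coupled Stuart-Landau oscillators,
//   dz_j/dt = (a_j + i w_j - |z_j|^2) z_j + sum_k C[j,k] (z_k - z_j) + eta_j,
// with independent Gaussian noise of SD sigma*sqrt(dt) added to the real and
// imaginary parts at each step.  Noise is drawn from R's RNG so set.seed()
// on the R side controls the trajectory.  Samples Re(z) every
// steps_per_sample steps after discarding n_discard steps; the first sample
// is taken immediately after the transient.
// [[Rcpp::export]]
List hopf_sim_cpp(NumericVector a, NumericVector omega, double sigma,
                  NumericMatrix C, double dt, int n_samples,
                  int steps_per_sample, int n_discard,
                  NumericVector z0_re, NumericVector z0_im) {
  const int M = a.size();
  std::vector<double> zr(z0_re.begin(), z0_re.end());
  std::vector<double> zi(z0_im.begin(), z0_im.end());
  std::vector<double> dzr(M), dzi(M);
  NumericMatrix out(n_samples, M);
  const double sq = sigma * std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  const long total = (long)n_discard + (long)(n_samples - 1) * steps_per_sample;
  int sample_idx = 0;

  for (long step = 0;; ++step) {
    if (step >= n_discard && (step - n_discard) % steps_per_sample == 0) {
      for (int j = 0; j < M; ++j) out(sample_idx, j) = zr[j];
      ++sample_idx;
    }
    if (step >= total) break;
    for (int j = 0; j < M; ++j) {
      const double r2 = zr[j] * zr[j] + zi[j] * zi[j];
      double cr = 0.0, ci = 0.0;
      for (int k = 0; k < M; ++k) {
        const double cjk = C(j, k);
        if (cjk != 0.0) {
          cr += cjk * (zr[k] - zr[j]);
          ci += cjk * (zi[k] - zi[j]);
        }
      }
      dzr[j] = (a[j] - r2) * zr[j] - omega[j] * zi[j] + cr;
      dzi[j] = (a[j] - r2) * zi[j] + omega[j] * zr[j] + ci;
    }
    for (int j = 0; j < M; ++j) {
      zr[j] += dt * dzr[j];
      zi[j] += dt * dzi[j];
      if (noisy) {
        zr[j] += sq * norm_rand();
        zi[j] += sq * norm_rand();
      }
      if (std::fabs(zr[j]) > 1e6 || std::fabs(zi[j]) > 1e6)
        stop("Hopf integration blew up (|z| > 1e6) at step %ld; "
             "reduce dt or the coupling strength", step);
    }
  }

  NumericVector zfr(M), zfi(M);
  for (int j = 0; j < M; ++j) { zfr[j] = zr[j]; zfi[j] = zi[j]; }
  return List::create(_["x"] = out, _["z_re"] = zfr, _["z_im"] = zfi);
}
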