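#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Batched model observables for LGEC inference: runs n_sims independent
// Stuart-Landau simulations and returns the averaged zero-lag FC and
// forward-shifted FCf(tau).  The inference loop calls this thousands of
// times, so it uses an internal xoshiro256++ RNG (seeded explicitly from the
// R side) and a ziggurat normal generator instead of R's RNG.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  int32_t next32() { return (int32_t)(next() >> 32); }
};

// Marsaglia-Tsang 128-layer ziggurat for standard normals.
struct ZigguratNormal {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigguratNormal() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double draw(Xoshiro256pp& rng) const {
    for (;;) {
      const int32_t hz = rng.next32();
      const int iz = hz & 127;
      if ((uint32_t)std::llabs((long long)hz) < kn[iz]) return hz * wn[iz];
      // slow path
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      // otherwise retry with a fresh draw
    }
  }
};

const ZigguratNormal& ziggurat() {
  static const ZigguratNormal z;
  return z;
}

// One simulation writing Re(z) samples into out (n_samples x M, column-major
// slice of a flat buffer).
void simulate_one(const double* a, const double* omega, double sigma,
                  const double* C, int M, double dt, int n_samples,
                  int steps_per_sample, int n_discard, Xoshiro256pp& rng,
                  std::vector<double>& out) {
  const ZigguratNormal& zig = ziggurat();
  std::vector<double> zr(M), zi(M), dzr(M), dzi(M);
  // row-major copy of C and its row sums: sum_k C_jk (z_k - z_j)
  // = (Crow_j . z) - rowsum_j * z_j, a dense branch-free matvec
  std::vector<double> Crow((size_t)M * M), rowsum(M, 0.0);
  for (int j = 0; j < M; ++j)
    for (int k = 0; k < M; ++k) {
      const double cjk = C[(size_t)j + (size_t)k * M];
      Crow[(size_t)j * M + k] = cjk;
      rowsum[j] += cjk;
    }
  for (int j = 0; j < M; ++j) {
    zr[j] = 0.1 * zig.draw(rng);
    zi[j] = 0.1 * zig.draw(rng);
  }
  const double sq = sigma * std::sqrt(dt);
  const long total = (long)n_discard + (long)(n_samples - 1) * steps_per_sample;
  int sample_idx = 0;
  for (long step = 0;; ++step) {
    if (step >= n_discard && (step - n_discard) % steps_per_sample == 0) {
      for (int j = 0; j < M; ++j) out[(size_t)j * n_samples + sample_idx] = zr[j];
      ++sample_idx;
    }
    if (step >= total) break;
    for (int j = 0; j < M; ++j) {
      const double r2 = zr[j] * zr[j] + zi[j] * zi[j];
      const double* Cj = &Crow[(size_t)j * M];
      double sr = 0.0, si = 0.0;
      for (int k = 0; k < M; ++k) {
        sr += Cj[k] * zr[k];
        si += Cj[k] * zi[k];
      }
      const double g = a[j] - r2 - rowsum[j];
      dzr[j] = g * zr[j] - omega[j] * zi[j] + sr;
      dzi[j] = g * zi[j] + omega[j] * zr[j] + si;
    }
    for (int j = 0; j < M; ++j) {
      zr[j] += dt * dzr[j] + sq * zig.draw(rng);
      zi[j] += dt * dzi[j] + sq * zig.draw(rng);
      if (std::fabs(zr[j]) > 1e6 || std::fabs(zi[j]) > 1e6)
        stop("Hopf integration blew up (|z| > 1e6); reduce dt or coupling");
    }
  }
}

// Pearson correlation between columns of x with a forward shift of tau
// frames applied to the second column; tau = 0 gives plain FC.
void corr_shift(const std::vector<double>& x, int T, int M, int tau,
                std::vector<double>& out) {
  const int L = T - tau;
  std::vector<double> me(M), ml(M), se(M), sl(M);
  for (int j = 0; j < M; ++j) {
    const double* col = x.data() + (size_t)j * T;
    double s1 = 0, s2 = 0;
    for (int t = 0; t < L; ++t) s1 += col[t];
    for (int t = tau; t < T; ++t) s2 += col[t];
    me[j] = s1 / L;
    ml[j] = s2 / L;
    double v1 = 0, v2 = 0;
    for (int t = 0; t < L; ++t) v1 += (col[t] - me[j]) * (col[t] - me[j]);
    for (int t = tau; t < T; ++t) v2 += (col[t] - ml[j]) * (col[t] - ml[j]);
    se[j] = std::sqrt(v1);
    sl[j] = std::sqrt(v2);
  }
  for (int i = 0; i < M; ++i) {
    const double* ci = x.data() + (size_t)i * T;
    for (int j = 0; j < M; ++j) {
      const double* cj = x.data() + (size_t)j * T;
      double cp = 0;
      for (int t = 0; t < L; ++t)
        cp += (ci[t] - me[i]) * (cj[t + tau] - ml[j]);
      const double denom = se[i] * sl[j];
      out[(size_t)i + (size_t)j * M] = denom > 0 ? cp / denom : 0.0;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List hopf_obs_batch_cpp(NumericVector a, NumericVector omega, double sigma,
                        NumericMatrix C, double dt, int n_samples,
                        int steps_per_sample, int n_discard, int n_sims,
                        int tau, double seed) {
  const int M = a.size();
  const int T = n_samples;
  NumericMatrix fc(M, M), fcf(M, M);
  std::vector<double> x((size_t)T * M), cm((size_t)M * M);
  Xoshiro256pp rng((uint64_t)seed);
  for (int s = 0; s < n_sims; ++s) {
    simulate_one(REAL(a), REAL(omega), sigma, REAL(C), M, dt, T,
                 steps_per_sample, n_discard, rng, x);
    corr_shift(x, T, M, 0, cm);
    for (int k = 0; k < M * M; ++k) fc[k] += cm[k];
    corr_shift(x, T, M, tau, cm);
    for (int k = 0; k < M * M; ++k) fcf[k] += cm[k];
  }
  for (int k = 0; k < M * M; ++k) { fc[k] /= n_sims; fcf[k] /= n_sims; }
  for (int j = 0; j < M; ++j) fc(j, j) = 1.0;
  return List::create(_["fc"] = fc, _["fcf"] = fcf);
}
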