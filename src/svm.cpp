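#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Kernel SVM trained by sequential minimal optimisation (SMO) with
// maximal-violating-pair working-set selection, plus a one-versus-one
// multiclass wrapper with vote / summed-decision tie-breaking.
// No R SVM implementation ships in this stack, so the solver lives here.

namespace {

// Binary SMO on a precomputed dense kernel submatrix.
// Kd: n x n kernel, row-major; y in {-1, +1}.
void smo_train(const std::vector<double>& Kd,
               const std::vector<int>& y, int n, double Cbox, double eps,
               int max_iter, std::vector<double>& alpha, double& b) {
  auto K = [&](int i, int j) { return Kd[(size_t)i * n + j]; };
  alpha.assign(n, 0.0);
  // G[t] = sum_s alpha[s] y[s] K(s, t)   (decision value without bias)
  std::vector<double> G(n, 0.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // F[t] = y[t] - G[t]; select i = argmax F over I_up, j = argmin over I_low
    int i = -1, j = -1;
    double Fmax = -1e300, Fmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const double F = y[t] - G[t];
      const bool up = (y[t] == 1 && alpha[t] < Cbox) ||
                      (y[t] == -1 && alpha[t] > 0.0);
      const bool low = (y[t] == -1 && alpha[t] < Cbox) ||
                       (y[t] == 1 && alpha[t] > 0.0);
      if (up && F > Fmax) { Fmax = F; i = t; }
      if (low && F < Fmin) { Fmin = F; j = t; }
    }
    if (i < 0 || j < 0 || Fmax - Fmin < eps) break;

    // Platt's analytic two-variable solve for the pair (i, j)
    const double s = (double)y[i] * y[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(Cbox, Cbox + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - Cbox);
      H = std::min(Cbox, alpha[i] + alpha[j]);
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    const double Ei = G[i] - y[i], Ej = G[j] - y[j];
    double aj = alpha[j] + y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    const double ai = alpha[i] + s * (alpha[j] - aj);
    const double di = ai - alpha[i], dj = aj - alpha[j];
    if (std::fabs(dj) < 1e-14 && std::fabs(di) < 1e-14) break;
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[i] * di * K(i, t) + y[j] * dj * K(j, t);
  }

  // bias from the KKT interval midpoint (free SVs collapse it to a point)
  double bup = -1e300, blow = 1e300;
  for (int t = 0; t < n; ++t) {
    const double F = y[t] - G[t];
    const bool up = (y[t] == 1 && alpha[t] < Cbox) ||
                    (y[t] == -1 && alpha[t] > 0.0);
    const bool low = (y[t] == -1 && alpha[t] < Cbox) ||
                     (y[t] == 1 && alpha[t] > 0.0);
    if (up && F > bup) bup = F;
    if (low && F < blow) blow = F;
  }
  b = 0.5 * (bup + blow);
}

// contiguous (point-major) copy of an R matrix, one point per row
inline std::vector<double> to_rowmajor(const NumericMatrix& A) {
  const int n = A.nrow(), D = A.ncol();
  std::vector<double> out((size_t)n * D);
  for (int c = 0; c < D; ++c)
    for (int i = 0; i < n; ++i) out[(size_t)i * D + c] = A(i, c);
  return out;
}

inline double sqdist(const double* a, const double* b, int D) {
  double d = 0.0;
  for (int c = 0; c < D; ++c) {
    const double u = a[c] - b[c];
    d += u * u;
  }
  return d;
}

}  // namespace

// One-versus-one Gaussian-kernel SVM: train on (Xtr, ytr in 1..K), predict
// labels for Xte by voting over the K(K-1)/2 binary machines; ties broken by
// the summed signed decision values.
// [[Rcpp::export]]
IntegerVector svm_ovo_cpp(NumericMatrix Xtr, IntegerVector ytr,
                          NumericMatrix Xte, int K, double Cbox, double gamma,
                          double eps, int max_iter) {
  const int n = Xtr.nrow(), m = Xte.nrow();
  const int D = Xtr.ncol();
  const std::vector<double> xtr = to_rowmajor(Xtr);
  const std::vector<double> xte = to_rowmajor(Xte);

  // full train kernel (n is a few hundred in practice)
  std::vector<double> Kfull((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      const double v =
          std::exp(-gamma * sqdist(&xtr[(size_t)i * D], &xtr[(size_t)j * D], D));
      Kfull[(size_t)i * n + j] = v;
      Kfull[(size_t)j * n + i] = v;
    }

  std::vector<std::vector<int>> by_class(K + 1);
  for (int i = 0; i < n; ++i) by_class[ytr[i]].push_back(i);

  std::vector<std::vector<int>> votes(m, std::vector<int>(K + 1, 0));
  std::vector<std::vector<double>> dsum(m, std::vector<double>(K + 1, 0.0));

  for (int p = 1; p <= K; ++p) {
    for (int q = p + 1; q <= K; ++q) {
      std::vector<int> idx;
      std::vector<int> y;
      for (int t : by_class[p]) { idx.push_back(t); y.push_back(+1); }
      for (int t : by_class[q]) { idx.push_back(t); y.push_back(-1); }
      const int nb = (int)idx.size();
      if (by_class[p].empty() || by_class[q].empty())
        stop("class %d or %d absent from the training set", p, q);
      std::vector<double> Ksub((size_t)nb * nb);
      for (int i = 0; i < nb; ++i)
        for (int j = 0; j < nb; ++j)
          Ksub[(size_t)i * nb + j] = Kfull[(size_t)idx[i] * n + idx[j]];
      std::vector<double> alpha;
      double b;
      smo_train(Ksub, y, nb, Cbox, eps, max_iter, alpha, b);
      for (int t = 0; t < m; ++t) {
        double f = b;
        for (int i = 0; i < nb; ++i) {
          if (alpha[i] > 0.0)
            f += alpha[i] * y[i] *
                 std::exp(-gamma * sqdist(&xtr[(size_t)idx[i] * D],
                                          &xte[(size_t)t * D], D));
        }
        if (f >= 0.0) votes[t][p] += 1; else votes[t][q] += 1;
        dsum[t][p] += f;
        dsum[t][q] -= f;
      }
    }
  }

  IntegerVector pred(m);
  for (int t = 0; t < m; ++t) {
    int best = 1;
    for (int c = 2; c <= K; ++c) {
      if (votes[t][c] > votes[t][best] ||
          (votes[t][c] == votes[t][best] && dsum[t][c] > dsum[t][best]))
        best = c;
    }
    pred[t] = best;
  }
  return pred;
}
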