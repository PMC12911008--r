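// Compiled kernels for the weighted graph metrics: all-pairs shortest paths
// (Floyd-Warshall on 1/weight lengths) and nodal local efficiency. These are
// O(P^3) and sit in the inner loop of the null-ensemble normalization.
#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static void fw_inplace(std::vector<double>& d, int p) {
  const double inf = std::numeric_limits<double>::infinity();
  for (int k = 0; k < p; ++k) {
    const double* dk_col = &d[(size_t)k * p];
    for (int j = 0; j < p; ++j) {
      const double dkj = d[(size_t)j * p + k];
      if (dkj == inf) continue;
      double* dj = &d[(size_t)j * p];
      for (int i = 0; i < p; ++i) {
        const double via = dk_col[i] + dkj;
        if (via < dj[i]) dj[i] = via;
      }
    }
  }
}

// [[Rcpp::export(name = ".fw_dist_cpp")]]
NumericMatrix fw_dist_cpp(NumericMatrix adj) {
  const int p = adj.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t)p * p, inf);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i) {
      const double w = adj(i, j);
      if (w > 0) d[(size_t)j * p + i] = 1.0 / w;
    }
  for (int i = 0; i < p; ++i) d[(size_t)i * p + i] = 0.0;
  fw_inplace(d, p);
  NumericMatrix out(p, p);
  std::copy(d.begin(), d.end(), out.begin());
  return out;
}

// mean nodal neighbor-subgraph efficiency (local efficiency)
// [[Rcpp::export(name = ".local_eff_cpp")]]
double local_eff_cpp(NumericMatrix adj) {
  const int p = adj.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  double total = 0.0;
  std::vector<int> nb;
  std::vector<double> d;
  for (int v = 0; v < p; ++v) {
    nb.clear();
    for (int i = 0; i < p; ++i)
      if (adj(i, v) > 0) nb.push_back(i);
    const int m = (int)nb.size();
    if (m < 2) continue;
    d.assign((size_t)m * m, inf);
    for (int j = 0; j < m; ++j) {
      d[(size_t)j * m + j] = 0.0;
      for (int i = 0; i < m; ++i) {
        const double w = adj(nb[i], nb[j]);
        if (i != j && w > 0) d[(size_t)j * m + i] = 1.0 / w;
      }
    }
    fw_inplace(d, m);
    double s = 0.0;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i)
        if (i != j && d[(size_t)j * m + i] < inf)
          s += 1.0 / d[(size_t)j * m + i];
    total += s / ((double)m * (m - 1));
  }
  return total / p;
}

// Conv1D (ReLU) + non-overlapping max-pool over the ordered upper-triangle
// vector: forward pass returning the flattened pooled maps plus the argmax
// positions, and the matching backward pass for the kernel/bias gradients.
// [[Rcpp::export(name = ".conv_pool_fwd_cpp")]]
List conv_pool_fwd_cpp(NumericMatrix X, NumericMatrix K, NumericVector bias,
                       int stride, int pool) {
  const int B = X.nrow(), L = X.ncol();
  const int k = K.nrow(), F = K.ncol();
  const int Lc = (L - k) / stride + 1;
  const int Lp = Lc / pool;
  NumericMatrix flat(B, Lp * F);
  IntegerMatrix amax(B, Lp * F);
  for (int f = 0; f < F; ++f) {
    const double* kf = &K(0, f);
    const double bf = bias[f];
    for (int b = 0; b < B; ++b) {
      for (int u = 0; u < Lp; ++u) {
        double best = 0.0;   // ReLU floor: all-negative windows pool to 0
        int bestt = -1;
        for (int v = 0; v < pool; ++v) {
          const int t = u * pool + v;
          const int start = t * stride;
          double z = bf;
          for (int j = 0; j < k; ++j) z += X(b, start + j) * kf[j];
          if (z > best) { best = z; bestt = t; }
        }
        flat(b, u + (long)f * Lp) = best;
        amax(b, u + (long)f * Lp) = bestt;
      }
    }
  }
  return List::create(_["flat"] = flat, _["amax"] = amax);
}

// [[Rcpp::export(name = ".conv_pool_bwd_cpp")]]
List conv_pool_bwd_cpp(NumericMatrix X, NumericMatrix dflat,
                       IntegerMatrix amax, int k, int F, int stride) {
  const int B = X.nrow();
  const int Lp = dflat.ncol() / F;
  NumericMatrix dK(k, F);
  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    for (int b = 0; b < B; ++b) {
      for (int u = 0; u < Lp; ++u) {
        const int t = amax(b, u + (long)f * Lp);
        if (t < 0) continue;             // pooled output was clipped at 0
        const double g = dflat(b, u + (long)f * Lp);
        if (g == 0.0) continue;
        db[f] += g;
        const int start = t * stride;
        for (int j = 0; j < k; ++j) dK(j, f) += g * X(b, start + j);
      }
    }
  }
  return List::create(_["dK"] = dK, _["db"] = db);
}
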