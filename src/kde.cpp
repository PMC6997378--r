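#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

// Gaussian pdf with sd s evaluated at distance d
static inline double gpdf(double d, double s) {
  double z = d / s;
  return INV_SQRT_2PI / s * std::exp(-0.5 * z * z);
}

// type-7 quantile on a copy of x
static double quantile7(std::vector<double> x, double p) {
  const int n = (int)x.size();
  if (n == 1) return x[0];
  std::sort(x.begin(), x.end());
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// Least-squares leave-one-out CV bandwidth selection, per voxel (rows of X).
// CV(h) = \int fhat^2 - (2/N) sum_n fhat_{-n}(X_n), with the integral in
// closed form (pairwise Gaussian at sd h*sqrt(2)) and the leave-one-out
// density renormalized over the remaining N-1 kernels. Candidates are
// rel_grid * sample SD of the row; ties broken toward the smallest h.
// Rows with zero sample SD are flagged invalid (h = NA).
// [[Rcpp::export]]
List cpp_select_bandwidth(NumericMatrix X, NumericVector rel_grid) {
  const int V = X.nrow(), N = X.ncol(), G = rel_grid.size();
  if (N < 2) stop("bandwidth selection requires at least 2 observations");
  NumericVector h_out(V);
  LogicalVector valid(V);
  const int P = N * (N - 1) / 2;
  std::vector<double> d2(P);

  for (int v = 0; v < V; ++v) {
    double m = 0.0;
    for (int i = 0; i < N; ++i) m += X(v, i);
    m /= N;
    double ss = 0.0;
    for (int i = 0; i < N; ++i) { double c = X(v, i) - m; ss += c * c; }
    double sd = std::sqrt(ss / (N - 1));
    if (!(sd > 0.0) || !R_finite(sd)) {
      h_out[v] = NA_REAL; valid[v] = false; continue;
    }
    int k = 0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double d = X(v, i) - X(v, j);
        d2[k++] = d * d;
      }
    std::sort(d2.begin(), d2.end());  // ascending: allows early exit below
    double best = R_PosInf, best_h = NA_REAL;
    for (int g = 0; g < G; ++g) {
      double h = rel_grid[g] * sd;
      double s2h  = 2.0 * h * h;   // 2 * h^2
      double c2 = INV_SQRT_2PI / (h * M_SQRT2);  // pdf scale at sd h*sqrt2
      double c1 = INV_SQRT_2PI / h;              // pdf scale at sd h
      double sum2 = 0.0, sum1 = 0.0;
      // e1 = exp(-d2/(2h^2)); exp(-d2/(4h^2)) = sqrt(e1); terms vanish
      // once d2/(2h^2) is large, so stop early on the sorted distances
      for (int p = 0; p < P; ++p) {
        double e1 = std::exp(-d2[p] / s2h);
        sum1 += e1;
        sum2 += std::sqrt(e1);
        if (d2[p] > 160.0 * s2h) break;  // sqrt(e1) < 4e-35 beyond here
      }
      double integral = (N * c2 + 2.0 * c2 * sum2) / ((double)N * N);
      double loo = 4.0 * c1 * sum1 / ((double)N * (N - 1));
      double cv = integral - loo;
      if (cv < best) { best = cv; best_h = h; }
    }
    h_out[v] = best_h; valid[v] = true;
  }
  return List::create(_["h"] = h_out, _["valid"] = valid);
}

// Hampel psi(d)/d with breakpoints a <= b <= c
static inline double hampel_w(double d, double a, double b, double c) {
  if (d < a) return 1.0;
  if (d < b) return a / d;
  if (d < c) {
    if (c <= b) return 0.0;
    return a * (c - d) / ((c - b) * d);
  }
  return 0.0;
}

// Robust KDE kernel weights per voxel: iteratively reweighted fit in the
// kernel-induced (RKHS) geometry. Each point's distance to the current
// weighted mixture is d_n^2 = k(0) - 2 (Kw)_n + w'Kw; weights are set
// proportional to psi(d)/d for the Hampel psi, with breakpoints a, b taken
// as quantiles (q_a, q_b) of the initial (uniform-weight) distance
// distribution and c = c_scale * its maximum. Converged when
// max |w change| < tol.
// [[Rcpp::export]]
List cpp_robust_weights(NumericMatrix X, NumericVector h,
                        double tol, int max_iter,
                        double q_a, double q_b, double c_scale) {
  const int V = X.nrow(), N = X.ncol();
  NumericMatrix W(V, N);
  LogicalVector converged(V);
  IntegerVector iters(V);

  std::vector<double> K((size_t)N * N), w(N), wnew(N), Kw(N), d(N), d2(N);

  for (int v = 0; v < V; ++v) {
    if (!R_finite(h[v]) || !(h[v] > 0)) {
      for (int i = 0; i < N; ++i) W(v, i) = NA_REAL;
      converged[v] = false; iters[v] = 0;
      continue;
    }
    if (N == 1) { W(v, 0) = 1.0; converged[v] = true; iters[v] = 0; continue; }
    const double hv = h[v];
    const double k0 = INV_SQRT_2PI / hv;
    for (int i = 0; i < N; ++i) {
      K[(size_t)i * N + i] = k0;
      for (int j = i + 1; j < N; ++j) {
        double val = gpdf(X(v, i) - X(v, j), hv);
        K[(size_t)i * N + j] = val;
        K[(size_t)j * N + i] = val;
      }
    }
    for (int i = 0; i < N; ++i) w[i] = 1.0 / N;
    double a = 0, b = 0, c = 0;
    bool conv = false;
    int it = 0;
    for (it = 0; it <= max_iter; ++it) {
      // distances under current weights
      double quad = 0.0;
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        const double *Ki = &K[(size_t)i * N];
        for (int j = 0; j < N; ++j) s += Ki[j] * w[j];
        Kw[i] = s;
      }
      for (int i = 0; i < N; ++i) quad += w[i] * Kw[i];
      for (int i = 0; i < N; ++i) {
        double dd = k0 - 2.0 * Kw[i] + quad;
        if (dd < 0) dd = 0;
        d2[i] = dd;
        d[i] = std::sqrt(dd);
      }
      if (it == 0) {
        a = quantile7(std::vector<double>(d.begin(), d.end()), q_a);
        b = quantile7(std::vector<double>(d.begin(), d.end()), q_b);
        c = c_scale * *std::max_element(d.begin(), d.end());
        if (!(c > 0)) { conv = true; break; }  // all points coincide with mixture
      }
      double sum = 0.0;
      for (int i = 0; i < N; ++i) {
        double psi = (d[i] <= 0) ? 1.0 : hampel_w(d[i], a, b, c);
        wnew[i] = psi;
        sum += psi;
      }
      if (!(sum > 0)) {  // pathological: everything beyond c; keep last iterate
        conv = false;
        break;
      }
      double delta = 0.0;
      for (int i = 0; i < N; ++i) {
        wnew[i] /= sum;
        double ch = std::fabs(wnew[i] - w[i]);
        if (ch > delta) delta = ch;
        w[i] = wnew[i];
      }
      if (delta < tol) { conv = true; break; }
    }
    for (int i = 0; i < N; ++i) W(v, i) = w[i];
    converged[v] = conv;
    iters[v] = it;
  }
  return List::create(_["weights"] = W, _["converged"] = converged,
                      _["iters"] = iters);
}

// Weighted Gaussian-mixture CDF evaluated at one query per voxel:
// P_v = sum_n W(v,n) * Phi((x_v - X(v,n)) / h_v)
// [[Rcpp::export]]
NumericVector cpp_kde_cdf_batch(NumericMatrix X, NumericMatrix W,
                                NumericVector h, NumericVector x) {
  const int V = X.nrow(), N = X.ncol();
  NumericVector out(V);
  for (int v = 0; v < V; ++v) {
    if (!R_finite(h[v]) || !(h[v] > 0) || !R_finite(x[v])) {
      out[v] = NA_REAL; continue;
    }
    double s = 0.0;
    for (int n = 0; n < N; ++n)
      s += W(v, n) * R::pnorm(x[v], X(v, n), h[v], 1, 0);
    out[v] = s;
  }
  return out;
}
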