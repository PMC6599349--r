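// Sparse inverse-covariance estimation by the graphical lasso block
// coordinate descent, plus a Kendall tau-b matrix used by the SKEPTIC
// correlation estimator.  Compiled because both sit inside permutation
// and bootstrap loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso solve for fixed lambda.  Penalty on off-diagonal entries of the
// precision matrix only (diagonal of the working covariance W stays at
// diag(S)).  W and B carry warm starts across a lambda path; B(k, j) is the
// lasso coefficient of variable k in the regression for column j.
static void glasso_solve(const arma::mat& S, double lambda,
                         arma::mat& W, arma::mat& B, arma::mat& K,
                         double tol, double gap_tol, int maxit,
                         int& niter, double& gap) {
  const int p = S.n_cols;
  const double off_mean = (p > 1)
    ? arma::accu(arma::abs(S - arma::diagmat(S))) / (p * (p - 1))
    : 0.0;
  const double thr = tol * std::max(off_mean, 1e-12);

  const double inner_thr = std::max(1e-9, 0.05 * thr);
  gap = R_PosInf;
  niter = 0;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      // inner lasso: minimise 0.5 b' W11 b - s12' b + lambda ||b||_1
      for (int inner = 0; inner < 1000; ++inner) {
        double bmax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bnew = soft(r, lambda) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > bmax) bmax = d;
          B(k, j) = bnew;
        }
        if (bmax < inner_thr) break;
      }
      // w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > dmax) dmax = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    niter = it + 1;

    // recover K from (W, B) and check the duality gap
    for (int j = 0; j < p; ++j) {
      double denom = W(j, j);
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        denom -= W(k, j) * B(k, j);
      }
      K(j, j) = 1.0 / denom;
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        K(k, j) = -B(k, j) / denom;
      }
    }
    K = 0.5 * (K + K.t());
    double l1_off = 0.0;
    for (int a = 0; a < p; ++a)
      for (int b = 0; b < p; ++b)
        if (a != b) l1_off += std::fabs(K(a, b));
    gap = arma::dot(arma::vectorise(S), arma::vectorise(K)) - p
      + lambda * l1_off;
    if (dmax < thr && gap < gap_tol) break;
  }
}

// [[Rcpp::export(name = ".glassoCpp")]]
List glasso_cpp(const arma::mat& S, double lambda,
                double tol = 1e-4, double gap_tol = 1e-6, int maxit = 1000) {
  const int p = S.n_cols;
  arma::mat W = S, B(p, p, arma::fill::zeros), K(p, p, arma::fill::zeros);
  int niter = 0;
  double gap = 0.0;
  glasso_solve(S, lambda, W, B, K, tol, gap_tol, maxit, niter, gap);
  return List::create(_["K"] = K, _["W"] = W, _["gap"] = gap,
                      _["niter"] = niter);
}

// Warm-started descent along a decreasing lambda path.  Returns the
// precision matrices plus log det K and tr(SK) for information-criterion
// evaluation in R.
// [[Rcpp::export(name = ".glassoPathCpp")]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     double tol = 1e-4, double gap_tol = 1e-6,
                     int maxit = 1000) {
  const int p = S.n_cols;
  const int m = lambdas.n_elem;
  arma::mat W = S, B(p, p, arma::fill::zeros), K(p, p, arma::fill::zeros);
  arma::cube Ks(p, p, m);
  arma::vec logdets(m), trSK(m), gaps(m);
  arma::ivec niters(m), edges(m);
  for (int i = 0; i < m; ++i) {
    int niter = 0;
    double gap = 0.0;
    glasso_solve(S, lambdas(i), W, B, K, tol, gap_tol, maxit, niter, gap);
    Ks.slice(i) = K;
    double val, sign;
    arma::log_det(val, sign, K);
    logdets(i) = (sign > 0) ? val : R_NegInf;
    trSK(i) = arma::dot(arma::vectorise(S), arma::vectorise(K));
    gaps(i) = gap;
    niters(i) = niter;
    int e = 0;
    for (int a = 0; a < p; ++a)
      for (int b = a + 1; b < p; ++b)
        if (std::fabs(K(a, b)) > 1e-10) ++e;
    edges(i) = e;
  }
  return List::create(_["K"] = Ks, _["logdet"] = logdets, _["trSK"] = trSK,
                      _["gap"] = gaps, _["niter"] = niters,
                      _["E"] = edges);
}

// mergesort exchange count; equal keys are not exchanges
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          int lo, int hi) {
  if (hi - lo < 2) return 0.0;
  int mid = (lo + hi) / 2;
  double cnt = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      cnt += mid - i;
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return cnt;
}

// Kendall tau-b for one pair, Knight O(n log n) with tie corrections.
static double tau_b_pair(const arma::vec& x, const arma::vec& y) {
  const int n = x.n_elem;
  const double n0 = 0.5 * n * (n - 1.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  double tx = 0.0, ty = 0.0, txy = 0.0;
  // ties in x and joint ties, from the sorted order
  {
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && x[idx[j]] == x[idx[i]]) ++j;
      double t = j - i;
      tx += 0.5 * t * (t - 1.0);
      int a = i;
      while (a < j) {
        int b = a;
        while (b < j && y[idx[b]] == y[idx[a]]) ++b;
        double u = b - a;
        txy += 0.5 * u * (u - 1.0);
        a = b;
      }
      i = j;
    }
  }
  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  double swaps = merge_count(ys, buf, 0, n);  // ys now sorted
  {
    int i = 0;
    while (i < n) {
      int j = i;
      while (j < n && ys[j] == ys[i]) ++j;
      double t = j - i;
      ty += 0.5 * t * (t - 1.0);
      i = j;
    }
  }
  double den = std::sqrt((n0 - tx) * (n0 - ty));
  if (den <= 0.0) return NA_REAL;  // constant input
  double num = n0 - tx - ty + txy - 2.0 * swaps;
  return num / den;
}

// [[Rcpp::export(name = ".kendallTauCpp")]]
double kendall_tau_cpp(const arma::vec& x, const arma::vec& y) {
  return tau_b_pair(x, y);
}

// Pairwise tau-b matrix of the columns of X; NA where a column is constant.
// [[Rcpp::export(name = ".tauMatrixCpp")]]
arma::mat tau_matrix_cpp(const arma::mat& X) {
  const int p = X.n_cols;
  arma::mat T(p, p, arma::fill::eye);
  for (int a = 0; a < p; ++a) {
    for (int b = a + 1; b < p; ++b) {
      double t = tau_b_pair(X.col(a), X.col(b));
      T(a, b) = t;
      T(b, a) = t;
    }
  }
  return T;
}
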