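// Sign-permutation machinery for maximum-cluster-size inference.
// Exploits that sign flips leave per-point second moments unchanged, so the
// whole permutation-by-time t-value matrix is one matrix product plus
// elementwise transforms.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// empirical percentile: smallest sorted value with >= q*P values <= it
static double emp_quantile(vec v, const double q) {
  v = sort(v);
  uword idx = static_cast<uword>(std::ceil(q * v.n_elem));
  if (idx < 1) idx = 1;
  if (idx > v.n_elem) idx = v.n_elem;
  return v(idx - 1);
}

// transform signed-mean matrix M (P x T) into t-values in place;
// m2 = per-time sum of squares (fixed under sign flips), n = subjects
static void means_to_t(mat& M, const rowvec& m2, const double n) {
  const double big = 1e12;
  for (uword j = 0; j < M.n_cols; ++j) {
    for (uword i = 0; i < M.n_rows; ++i) {
      const double mean = M(i, j) / n;
      double var = (m2(j) - n * mean * mean) / (n - 1.0);
      if (var < 0) var = 0;
      const double se = std::sqrt(var / n);
      if (se > 0) {
        M(i, j) = mean / se;
      } else {
        M(i, j) = (mean > 0) ? big : (mean < 0 ? -big : 0.0);
      }
    }
  }
}

static uword max_run(const rowvec& t, const rowvec& thr) {
  uword best = 0, cur = 0;
  for (uword j = 0; j < t.n_elem; ++j) {
    if (t(j) > thr(j)) {
      if (++cur > best) best = cur;
    } else {
      cur = 0;
    }
  }
  return best;
}

// X: subjects x time (chance already subtracted); signs: P x n, row 0 must be
// the identity (all +1). Returns observed t-curve, per-time cluster-inducing
// thresholds (q-th percentile of the permutation t distribution) and the
// max-cluster-size null (one entry per permutation, identity included).
// [[Rcpp::export]]
Rcpp::List cpp_cluster_perm_1d(const arma::mat& X, const arma::mat& signs,
                               const double q) {
  const double n = static_cast<double>(X.n_rows);
  const rowvec m2 = sum(square(X), 0);
  mat M = signs * X;  // P x T sums
  means_to_t(M, m2, n);

  rowvec thresh(M.n_cols);
  for (uword j = 0; j < M.n_cols; ++j) thresh(j) = emp_quantile(M.col(j), q);

  vec null_max(M.n_rows);
  for (uword i = 0; i < M.n_rows; ++i)
    null_max(i) = static_cast<double>(max_run(M.row(i), thresh));

  return Rcpp::List::create(
      Rcpp::Named("t_obs") = rowvec(M.row(0)).t(),
      Rcpp::Named("thresh") = thresh.t(),
      Rcpp::Named("null_max") = null_max);
}

// max 4-connected component size on a T1 x T2 grid stored column-major
static uword max_component(const std::vector<char>& supra, const uword T1,
                           const uword T2, std::vector<char>& visited,
                           std::vector<uword>& stack) {
  std::fill(visited.begin(), visited.end(), 0);
  uword best = 0;
  const uword G = T1 * T2;
  for (uword g0 = 0; g0 < G; ++g0) {
    if (!supra[g0] || visited[g0]) continue;
    uword size = 0;
    stack.clear();
    stack.push_back(g0);
    visited[g0] = 1;
    while (!stack.empty()) {
      const uword g = stack.back();
      stack.pop_back();
      ++size;
      const uword i = g % T1, j = g / T1;
      const uword nb[4] = {(i > 0) ? g - 1 : G, (i + 1 < T1) ? g + 1 : G,
                           (j > 0) ? g - T1 : G, (j + 1 < T2) ? g + T1 : G};
      for (int k = 0; k < 4; ++k) {
        if (nb[k] < G && supra[nb[k]] && !visited[nb[k]]) {
          visited[nb[k]] = 1;
          stack.push_back(nb[k]);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// 2D analogue: X is subjects x (T1*T2) with matrices flattened column-major.
// [[Rcpp::export]]
Rcpp::List cpp_cluster_perm_2d(const arma::mat& X, const arma::mat& signs,
                               const double q, const int T1, const int T2) {
  const double n = static_cast<double>(X.n_rows);
  const rowvec m2 = sum(square(X), 0);
  mat M = signs * X;
  means_to_t(M, m2, n);

  rowvec thresh(M.n_cols);
  for (uword j = 0; j < M.n_cols; ++j) thresh(j) = emp_quantile(M.col(j), q);

  const uword G = static_cast<uword>(T1) * static_cast<uword>(T2);
  std::vector<char> supra(G), visited(G);
  std::vector<uword> stack;
  vec null_max(M.n_rows);
  for (uword i = 0; i < M.n_rows; ++i) {
    for (uword g = 0; g < G; ++g) supra[g] = M(i, g) > thresh(g);
    null_max(i) = static_cast<double>(
        max_component(supra, T1, T2, visited, stack));
  }

  return Rcpp::List::create(
      Rcpp::Named("t_obs") = rowvec(M.row(0)).t(),
      Rcpp::Named("thresh") = thresh.t(),
      Rcpp::Named("null_max") = null_max);
}

// label 4-connected components of a logical matrix; 0 = background
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_clusters_2d(const Rcpp::LogicalMatrix& supra) {
  const uword T1 = supra.nrow(), T2 = supra.ncol(), G = T1 * T2;
  std::vector<char> mask(G);
  for (uword j = 0; j < T2; ++j)
    for (uword i = 0; i < T1; ++i) mask[i + T1 * j] = supra(i, j) ? 1 : 0;

  Rcpp::IntegerMatrix labels(T1, T2);
  std::vector<char> visited(G, 0);
  std::vector<uword> stack;
  int next_label = 0;
  for (uword g0 = 0; g0 < G; ++g0) {
    if (!mask[g0] || visited[g0]) continue;
    ++next_label;
    stack.clear();
    stack.push_back(g0);
    visited[g0] = 1;
    while (!stack.empty()) {
      const uword g = stack.back();
      stack.pop_back();
      const uword i = g % T1, j = g / T1;
      labels(i, j) = next_label;
      const uword nb[4] = {(i > 0) ? g - 1 : G, (i + 1 < T1) ? g + 1 : G,
                           (j > 0) ? g - T1 : G, (j + 1 < T2) ? g + T1 : G};
      for (int k = 0; k < 4; ++k) {
        if (nb[k] < G && mask[nb[k]] && !visited[nb[k]]) {
          visited[nb[k]] = 1;
          stack.push_back(nb[k]);
        }
      }
    }
  }
  return labels;
}
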