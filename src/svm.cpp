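// Linear max-margin classification batched over time points and class pairs.
//
// The solver is dual coordinate descent for the L2-regularized hinge-loss
// (L1-loss) support vector classifier:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w'x_i)
// Instances carry an explicit constant feature, so the bias is part of w
// (regularized bias). The downstream scoring metric (ordering accuracy of
// two held-out samples) is invariant to the bias term, so this convention
// cannot affect reported accuracies.
//
// Training problems are tiny (tens of instances) but are solved tens of
// millions of times across time points, pairs, iterations and subjects. The
// time-course path therefore works entirely in Gram space: one
// (train+test)' (train+test) product per time point is shared by all class
// pairs, each pair solves its dual on a small Gram submatrix, and held-out
// decision values are read off the same Gram matrix.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double kTol = 1e-4;
static const int kMaxPass = 200;

// Dual coordinate descent on Q_ij = y_i y_j x_i'x_j. Returns alpha.
static vec solve_dual(const mat& Q, const double C) {
  const uword n = Q.n_rows;
  vec alpha(n, fill::zeros);
  vec qa(n, fill::zeros);  // Q * alpha, maintained incrementally
  for (int pass = 0; pass < kMaxPass; ++pass) {
    double max_pg = 0.0;
    for (uword i = 0; i < n; ++i) {
      if (Q(i, i) <= 0) continue;
      const double g = qa(i) - 1.0;
      double pg = g;
      if (alpha(i) <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha(i) >= C && g < 0.0) pg = 0.0;
      if (std::abs(pg) > max_pg) max_pg = std::abs(pg);
      if (std::abs(pg) > 1e-14) {
        const double a_old = alpha(i);
        double a_new = a_old - g / Q(i, i);
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        if (a_new != a_old) {
          alpha(i) = a_new;
          qa += (a_new - a_old) * Q.col(i);
        }
      }
    }
    if (max_pg < kTol) break;
  }
  return alpha;
}

static inline double order_score(const double dv_pos, const double dv_neg) {
  if (dv_pos > dv_neg) return 100.0;
  if (dv_pos < dv_neg) return 0.0;
  return 50.0;  // tie: the two-sample AUC value
}

// Explicit weight vector for one problem (columns of X are instances).
static vec svm_weights(const mat& X, const vec& y, const double C) {
  mat G = X.t() * X;
  const mat Q = G % (y * y.t());
  const vec alpha = solve_dual(Q, C);
  return X * (alpha % y);
}

// [[Rcpp::export]]
arma::vec cpp_svm_weights(const arma::mat& X, const arma::vec& y, double C) {
  return svm_weights(X, y, C);
}

struct PairProblem {
  uvec tr_idx;   // columns of the train block
  vec y;         // +1 for the positive (first) class
  uword ia, ib;  // columns of the test block holding the held-out samples
};

static std::vector<PairProblem> build_pairs(const ivec& train_cls,
                                            const ivec& test_cls,
                                            const imat& pairs) {
  std::vector<PairProblem> out(pairs.n_cols);
  for (uword p = 0; p < pairs.n_cols; ++p) {
    const sword a = pairs(0, p), b = pairs(1, p);
    out[p].tr_idx = find(train_cls == a || train_cls == b);
    out[p].y.set_size(out[p].tr_idx.n_elem);
    for (uword i = 0; i < out[p].tr_idx.n_elem; ++i)
      out[p].y(i) = (train_cls(out[p].tr_idx(i)) == a) ? 1.0 : -1.0;
    out[p].ia = as_scalar(find(test_cls == a, 1));
    out[p].ib = as_scalar(find(test_cls == b, 1));
  }
  return out;
}

// Time-resolved pairwise decoding for one iteration.
// train, test: cubes (features x instances x time); features include the
// constant bias row. pairs: 2 x n_pairs matrix of 0-based class ids, row 0
// the positive class. test holds exactly one instance per class referenced.
// Returns mean ordering accuracy across pairs, per time point.
// [[Rcpp::export]]
arma::vec cpp_decode_timecourse(const arma::cube& train,
                                const arma::ivec& train_cls,
                                const arma::cube& test,
                                const arma::ivec& test_cls,
                                const arma::imat& pairs,
                                double C) {
  const uword T = train.n_slices;
  const uword n_tr = train.n_cols, n_te = test.n_cols;
  const std::vector<PairProblem> pp = build_pairs(train_cls, test_cls, pairs);
  vec acc(T, fill::zeros);
  mat M(train.n_rows, n_tr + n_te);

  for (uword t = 0; t < T; ++t) {
    M.head_cols(n_tr) = train.slice(t);
    M.tail_cols(n_te) = test.slice(t);
    const mat G = M.t() * M;  // shared by all pairs at this time point
    for (const PairProblem& pr : pp) {
      const mat Gsub = G.submat(pr.tr_idx, pr.tr_idx);
      const mat Q = Gsub % (pr.y * pr.y.t());
      const vec alpha = solve_dual(Q, C);
      const vec ay = alpha % pr.y;
      double dva = 0.0, dvb = 0.0;
      for (uword i = 0; i < pr.tr_idx.n_elem; ++i) {
        dva += ay(i) * G(pr.tr_idx(i), n_tr + pr.ia);
        dvb += ay(i) * G(pr.tr_idx(i), n_tr + pr.ib);
      }
      acc(t) += order_score(dva, dvb);
    }
  }
  return acc / static_cast<double>(pairs.n_cols);
}

// Temporal generalization for one iteration: classifiers trained at each
// training time are evaluated at every testing time on the same held-out
// instances. Returns T_train x T_test accuracy (mean across pairs).
// [[Rcpp::export]]
arma::mat cpp_decode_tempgen(const arma::cube& train,
                             const arma::ivec& train_cls,
                             const arma::cube& test,
                             const arma::ivec& test_cls,
                             const arma::imat& pairs,
                             double C) {
  const uword T = train.n_slices;
  const uword Ttest = test.n_slices;
  const std::vector<PairProblem> pp = build_pairs(train_cls, test_cls, pairs);
  mat acc(T, Ttest, fill::zeros);

  for (const PairProblem& pr : pp) {
    mat Xa(test.n_rows, Ttest), Xb(test.n_rows, Ttest);
    for (uword tt = 0; tt < Ttest; ++tt) {
      Xa.col(tt) = test.slice(tt).col(pr.ia);
      Xb.col(tt) = test.slice(tt).col(pr.ib);
    }
    for (uword t = 0; t < T; ++t) {
      const mat Xtr = train.slice(t).cols(pr.tr_idx);
      const vec w = svm_weights(Xtr, pr.y, C);
      const rowvec dva = w.t() * Xa;
      const rowvec dvb = w.t() * Xb;
      for (uword tt = 0; tt < Ttest; ++tt)
        acc(t, tt) += order_score(dva(tt), dvb(tt));
    }
  }
  return acc / static_cast<double>(pairs.n_cols);
}

// Average trials into supertrials in one pass over the data array.
// data: trials x components x time (R array); group: 1-based supertrial id
// per trial, 0 = unused. Returns cube (components + 1) x n_super x time with
// the constant bias feature in the last row, ready for the decoders.
// [[Rcpp::export]]
arma::cube cpp_supertrials(const Rcpp::NumericVector& data_array,
                           const arma::ivec& group,
                           const int n_super, const int group_size) {
  const Rcpp::IntegerVector dims = data_array.attr("dim");
  // aliased view over the R array: no copy of the (large) epoch data
  const cube data(const_cast<double*>(data_array.begin()),
                  dims[0], dims[1], dims[2], false, true);
  const uword n_tr = data.n_rows, n_comp = data.n_cols, T = data.n_slices;
  cube out(n_comp + 1, n_super, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    for (uword c = 0; c < n_comp; ++c) {
      for (uword i = 0; i < n_tr; ++i) {
        const sword g = group(i);
        if (g > 0) out(c, g - 1, t) += data(i, c, t);
      }
    }
    for (int g = 0; g < n_super; ++g) {
      for (uword c = 0; c < n_comp; ++c) out(c, g, t) /= group_size;
      out(n_comp, g, t) = 1.0;
    }
  }
  return out;
}

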