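// Gaussian smoothing fused with decimation, column-wise on time-by-series
// matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Convolve each column of X (time x series) with a symmetric unit-sum kernel
// (given as full taps, odd length), using reflection at the edges, and keep
// only the rows in keep_idx (0-based). Computing only the retained samples
// fuses smoothing with decimation.
// [[Rcpp::export]]
arma::mat cpp_smooth_decimate(const arma::mat& X, const arma::vec& kernel,
                              const arma::uvec& keep_idx) {
  const sword T = static_cast<sword>(X.n_rows);
  const sword hw = (static_cast<sword>(kernel.n_elem) - 1) / 2;
  mat Y(keep_idx.n_elem, X.n_cols);
  for (uword j = 0; j < X.n_cols; ++j) {
    for (uword r = 0; r < keep_idx.n_elem; ++r) {
      const sword t = static_cast<sword>(keep_idx(r));
      double s = 0.0;
      for (sword k = -hw; k <= hw; ++k) {
        sword idx = t + k;
        if (idx < 0) idx = -idx;                    // reflect start
        if (idx >= T) idx = 2 * (T - 1) - idx;      // reflect end
        s += kernel(k + hw) * X(idx, j);
      }
      Y(r, j) = s;
    }
  }
  return Y;
}
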