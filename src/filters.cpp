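// Zero-phase IIR filtering of many timecourses at once.
// x is (n_series, n_time), column-major, so each time step is one
// contiguous column: the recursion runs over time with all series
// updated vectorially (direct form II transposed).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static void df2t_pass(mat& v, const vec& b, const vec& a, bool reverse) {
  const int ord = std::max(a.n_elem, b.n_elem) - 1;
  const int N = v.n_cols;
  vec bb(ord + 1, fill::zeros), aa(ord + 1, fill::zeros);
  for (uword i = 0; i < b.n_elem; ++i) bb(i) = b(i);
  for (uword i = 0; i < a.n_elem; ++i) aa(i) = a(i);
  // steady-state initial conditions for the first sample (so a constant
  // input passes through transient-free, the filtfilt convention)
  vec s(ord);
  s(ord - 1) = bb(ord) - aa(ord);
  for (int i = ord - 2; i >= 0; --i) s(i) = bb(i + 1) - aa(i + 1) + s(i + 1);
  mat z(v.n_rows, ord);
  const vec x0 = v.col(reverse ? N - 1 : 0);
  for (int i = 0; i < ord; ++i) z.col(i) = s(i) * x0;
  for (int tt = 0; tt < N; ++tt) {
    const int t = reverse ? N - 1 - tt : tt;
    vec xt = v.col(t);
    vec yt = bb(0) * xt + z.col(0);
    for (int i = 0; i < ord - 1; ++i)
      z.col(i) = bb(i + 1) * xt - aa(i + 1) * yt + z.col(i + 1);
    z.col(ord - 1) = bb(ord) * xt - aa(ord) * yt;
    v.col(t) = yt;
  }
}

// [[Rcpp::export]]
arma::mat iir_filtfilt(const arma::mat& x, const arma::vec& b,
                       const arma::vec& a) {
  const int n = x.n_cols;
  const int ord = std::max(a.n_elem, b.n_elem) - 1;
  const int npad = 3 * ord;
  if (n <= npad) Rcpp::stop("series too short for zero-phase filtering");
  mat xp(x.n_rows, n + 2 * npad);
  // odd (point-symmetric) reflection at both ends, the filtfilt convention
  for (int j = 0; j < npad; ++j)
    xp.col(j) = 2 * x.col(0) - x.col(npad - j);
  xp.cols(npad, npad + n - 1) = x;
  for (int j = 0; j < npad; ++j)
    xp.col(npad + n + j) = 2 * x.col(n - 1) - x.col(n - 2 - j);
  df2t_pass(xp, b, a, false);
  df2t_pass(xp, b, a, true);
  return xp.cols(npad, npad + n - 1);
}
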