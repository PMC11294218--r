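// Multi-head scaled dot-product attention cores.
// Token stacks arrive as (B*T) x (heads*dk) matrices whose row index is
// b + t*B (sample index varies fastest), matching the R-side flat2()
// layout.  Attention matrices travel as T x T x (heads*B) cubes with
// slice index h + heads*b, which reshapes on the R side to
// (T, T, heads, B) without copying.  Dropout masks are generated in R
// (so determinism flows from R's RNG) and passed in flat with the same
// layout as the attention cube; an empty mask disables dropout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline void softmax_rows_inplace(mat& s) {
  vec m = max(s, 1);
  s.each_col() -= m;
  s = exp(s);
  vec rs = sum(s, 1);
  s.each_col() /= rs;
}

// [[Rcpp::export(name = ".mha_core_fwd")]]
List mha_core_fwd(const arma::mat& Q, const arma::mat& K,
                  const arma::mat& V, int B, int T, int heads, int dk,
                  const arma::vec& dropmask) {
  const double scale = 1.0 / std::sqrt((double) dk);
  const bool use_mask = dropmask.n_elem > 0;
  mat O(Q.n_rows, Q.n_cols, fill::zeros);
  cube A(T, T, (uword) heads * B);
  uvec idx(T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) idx[t] = (uword) (b + t * B);
    for (int h = 0; h < heads; ++h) {
      uvec cols = regspace<uvec>((uword) h * dk, (uword) (h + 1) * dk - 1);
      mat q = Q.submat(idx, cols);
      mat k = K.submat(idx, cols);
      mat v = V.submat(idx, cols);
      mat s = q * k.t() * scale;
      softmax_rows_inplace(s);
      const uword sl = (uword) h + (uword) heads * b;
      A.slice(sl) = s;
      if (use_mask) {
        mat mk(const_cast<double*>(dropmask.memptr()) + sl * T * T,
               T, T, false, true);
        s %= mk;
      }
      O.submat(idx, cols) = s * v;
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// [[Rcpp::export(name = ".mha_core_bwd")]]
List mha_core_bwd(const arma::mat& Q, const arma::mat& K,
                  const arma::mat& V, const arma::cube& A,
                  const arma::mat& dO, int B, int T, int heads, int dk,
                  const arma::vec& dropmask) {
  const double scale = 1.0 / std::sqrt((double) dk);
  const bool use_mask = dropmask.n_elem > 0;
  mat dQ(Q.n_rows, Q.n_cols, fill::zeros);
  mat dK(Q.n_rows, Q.n_cols, fill::zeros);
  mat dV(Q.n_rows, Q.n_cols, fill::zeros);
  uvec idx(T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) idx[t] = (uword) (b + t * B);
    for (int h = 0; h < heads; ++h) {
      uvec cols = regspace<uvec>((uword) h * dk, (uword) (h + 1) * dk - 1);
      const uword sl = (uword) h + (uword) heads * b;
      const mat& a = A.slice(sl);
      mat dos = dO.submat(idx, cols);
      mat v = V.submat(idx, cols);
      mat ad = a, da;
      if (use_mask) {
        mat mk(const_cast<double*>(dropmask.memptr()) + sl * T * T,
               T, T, false, true);
        ad %= mk;
        da = (dos * v.t()) % mk;
      } else {
        da = dos * v.t();
      }
      dV.submat(idx, cols) = ad.t() * dos;
      vec rs = sum(da % a, 1);
      da.each_col() -= rs;
      mat ds = a % da;
      dQ.submat(idx, cols) = ds * K.submat(idx, cols) * scale;
      dK.submat(idx, cols) = ds.t() * Q.submat(idx, cols) * scale;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK,
                      Named("dV") = dV);
}

// inverted-dropout mask drawn from R's RNG (deterministic under set.seed)
// [[Rcpp::export(name = ".drop_mask")]]
Rcpp::NumericVector drop_mask(int n, double p) {
  Rcpp::NumericVector out(n);
  const double scale = 1.0 / (1.0 - p);
  GetRNGstate();
  for (int i = 0; i < n; ++i)
    out[i] = (unif_rand() >= p) ? scale : 0.0;
  PutRNGstate();
  return out;
}
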