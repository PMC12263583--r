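#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col: x is H x W x Cin, k x k kernel, zero padding `pad`, stride `stride`.
// Column ordering is (ki, kj, c) fastest-to-slowest; internal to fwd/bwd.
static mat im2col(const cube& x, int k, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  mat cols(Ho * Wo, k * k * Ci, fill::zeros);
  for (int c = 0; c < Ci; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + kj - pad;
          if (jj < 0 || jj >= Wd) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            cols(j * Ho + i, col) = x(ii, jj, c);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Co = w.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat out = cols * w;
  out.each_row() += b.t();
  cube O(Ho, Wo, Co);
  for (int c = 0; c < Co; ++c)
    O.slice(c) = reshape(out.col(c), Ho, Wo);
  return O;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w, int k,
                    int stride, int pad, const arma::cube& gout,
                    bool need_dx = true) {
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  const int Co = w.n_cols;
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  mat cols = im2col(x, k, stride, pad, Ho, Wo);
  mat g(Ho * Wo, Co);
  for (int c = 0; c < Co; ++c)
    g.col(c) = vectorise(gout.slice(c));
  mat dw = cols.t() * g;
  vec db = sum(g, 0).t();
  cube dx(need_dx ? H : 1, need_dx ? Wd : 1, need_dx ? Ci : 1,
          fill::zeros);
  if (!need_dx)
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  mat dcols = g * w.t();
  for (int c = 0; c < Ci; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + kj - pad;
          if (jj < 0 || jj >= Wd) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += dcols(j * Ho + i, col);
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
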