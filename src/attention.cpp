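#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// epsilon guard on token norms: cosine of a zero row is defined (zero vector),
// never NaN
static const double NORM_EPS = 1e-8;

// Scaled cosine attention over a batch of windows.
// F: n_tok x d_in x n_win token features, W: d_in x 3d joint QKV projection,
// inv_tau: 1/tau (tau > 0), B: n_tok x n_tok relative position bias shared
// across windows. Returns output tokens plus every intermediate needed by
// the backward pass.
// [[Rcpp::export]]
List cpp_win_attn_fwd(const arma::cube& F, const arma::mat& W,
                      double inv_tau, const arma::mat& B) {
  const uword n = F.n_rows, nw = F.n_slices;
  const uword d = W.n_cols / 3;
  cube Qr(n, d, nw), Kr(n, d, nw), V(n, d, nw);
  cube Qn(n, d, nw), Kn(n, d, nw);
  cube C(n, n, nw), A(n, n, nw), O(n, d, nw);

  for (uword s = 0; s < nw; ++s) {
    mat qkv = F.slice(s) * W;
    Qr.slice(s) = qkv.cols(0, d - 1);
    Kr.slice(s) = qkv.cols(d, 2 * d - 1);
    V.slice(s)  = qkv.cols(2 * d, 3 * d - 1);
    mat Qn_ = Qr.slice(s), Kn_ = Kr.slice(s);
    for (uword i = 0; i < n; ++i) {
      Qn_.row(i) /= (norm(Qr.slice(s).row(i), 2) + NORM_EPS);
      Kn_.row(i) /= (norm(Kr.slice(s).row(i), 2) + NORM_EPS);
    }
    mat Cs = Qn_ * Kn_.t();
    mat S = Cs * inv_tau + B;
    mat As(n, n);
    for (uword i = 0; i < n; ++i) {
      rowvec r = S.row(i);
      r -= r.max();
      rowvec e = exp(r);
      As.row(i) = e / accu(e);
    }
    Qn.slice(s) = Qn_; Kn.slice(s) = Kn_;
    C.slice(s) = Cs; A.slice(s) = As;
    O.slice(s) = As * V.slice(s);
  }
  return List::create(_["O"] = O, _["Qr"] = Qr, _["Kr"] = Kr, _["V"] = V,
                      _["Qn"] = Qn, _["Kn"] = Kn, _["C"] = C, _["A"] = A);
}

static rowvec norm_bwd(const rowvec& x, const rowvec& g) {
  // backward of x -> x / (||x|| + eps)
  double r = norm(x, 2);
  double den = r + NORM_EPS;
  rowvec dx = g / den;
  if (r > 1e-12) dx -= x * (dot(g, x) / (den * den * r));
  return dx;
}

// [[Rcpp::export]]
List cpp_win_attn_bwd(const arma::cube& F, const arma::mat& W, double inv_tau,
                      const arma::cube& Qr, const arma::cube& Kr,
                      const arma::cube& V, const arma::cube& Qn,
                      const arma::cube& Kn, const arma::cube& C,
                      const arma::cube& A, const arma::cube& dO) {
  const uword n = F.n_rows, nw = F.n_slices;
  const uword d = W.n_cols / 3;
  cube dF(size(F), fill::zeros);
  mat dW(size(W), fill::zeros);
  mat dB(n, n, fill::zeros);
  double d_invtau = 0.0;

  for (uword s = 0; s < nw; ++s) {
    mat dA = dO.slice(s) * V.slice(s).t();
    mat dV = A.slice(s).t() * dO.slice(s);
    mat dS(n, n);
    for (uword i = 0; i < n; ++i) {
      rowvec a = A.slice(s).row(i);
      rowvec da = dA.row(i);
      dS.row(i) = a % (da - dot(a, da));
    }
    dB += dS;
    d_invtau += accu(dS % C.slice(s));
    mat dC = dS * inv_tau;
    mat dQn = dC * Kn.slice(s);
    mat dKn = dC.t() * Qn.slice(s);
    mat dQ(n, d), dK(n, d);
    for (uword i = 0; i < n; ++i) {
      dQ.row(i) = norm_bwd(Qr.slice(s).row(i), dQn.row(i));
      dK.row(i) = norm_bwd(Kr.slice(s).row(i), dKn.row(i));
    }
    mat dQKV = join_rows(dQ, join_rows(dK, dV));
    dW += F.slice(s).t() * dQKV;
    dF.slice(s) = dQKV * W.t();
  }
  return List::create(_["dF"] = dF, _["dW"] = dW, _["dB"] = dB,
                      _["d_invtau"] = d_invtau);
}
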