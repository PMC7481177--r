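// Low-level 1-D CNN kernels.
//
// Batch layout: a batch of n signals of length L with C channels is stored as
// an (n*L) x C matrix whose row index is r = i + n*l (sample i fastest).
// This is the column-major flattening of an (n, L, C) array, so R can move
// between the matrix and array views without copying.
//
// Convolution weights: (k*Cin) x Cout, row index = j*Cin + c for kernel
// offset j (0-based) and input channel c.  "Same" zero padding, odd k.
//
// Convolutions run in single precision (the accuracy regime of mainstream
// deep-learning frameworks) for speed; inputs and outputs are double at the
// R boundary.  The im2col expansion built in the forward pass is cached as
// an external pointer and reused by the backward pass.  The conv activation
// (linear / ReLU / leaky-ReLU slope 0.3) is fused into the kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float LEAKY = 0.3f;

static fmat im2col1d(const fmat& X, int n, int L, int k) {
  const int Cin = X.n_cols;
  const int p = (k - 1) / 2;
  fmat Xc(static_cast<uword>(n) * L, static_cast<uword>(k) * Cin,
          fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int shift = j - p;
    const int l0 = std::max(0, -shift);
    const int l1 = std::min(L - 1, L - 1 - shift);
    if (l1 < l0) continue;
    Xc.submat(static_cast<uword>(n) * l0, static_cast<uword>(j) * Cin,
              static_cast<uword>(n) * (l1 + 1) - 1,
              static_cast<uword>(j) * Cin + Cin - 1) =
        X.rows(static_cast<uword>(n) * (l0 + shift),
               static_cast<uword>(n) * (l1 + shift + 1) - 1);
  }
  return Xc;
}

// act: 0 linear, 1 relu, 2 leaky
// [[Rcpp::export]]
Rcpp::List conv1d_fwd(const arma::mat& X, const arma::mat& W,
                      const arma::vec& b, int n, int L, int k, int act) {
  fmat Xf = conv_to<fmat>::from(X);
  fmat Wf = conv_to<fmat>::from(W);
  frowvec bf = conv_to<frowvec>::from(b.t());
  Rcpp::XPtr<fmat> xc(new fmat(im2col1d(Xf, n, L, k)), true);
  fmat Y = (*xc) * Wf;
  Y.each_row() += bf;
  if (act == 1) {
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  } else if (act == 2) {
    Y.transform([](float v) { return v > 0.0f ? v : LEAKY * v; });
  }
  return Rcpp::List::create(Rcpp::Named("Y") = conv_to<mat>::from(Y),
                            Rcpp::Named("xc") = xc);
}

// Backward through activation + convolution.  `Y` is the forward output
// (post-activation), used to recover the activation mask.  Set
// `need_dx = false` for the first layer of a network to skip the input
// gradient.
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(SEXP xc_ptr, const arma::mat& W, const arma::mat& dY,
                      const arma::mat& Y, int n, int L, int k, int act,
                      bool need_dx) {
  Rcpp::XPtr<fmat> xc(xc_ptr);
  const int Cin = W.n_rows / k;
  const int p = (k - 1) / 2;
  fmat dPre = conv_to<fmat>::from(dY);
  if (act == 1) {
    fmat Yf = conv_to<fmat>::from(Y);
    dPre.elem(find(Yf <= 0)).zeros();
  } else if (act == 2) {
    fmat Yf = conv_to<fmat>::from(Y);
    uvec neg = find(Yf <= 0);
    dPre.elem(neg) *= LEAKY;
  }
  fmat dW = xc->t() * dPre;
  frowvec db = sum(dPre, 0);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = conv_to<vec>::from(db.t()),
      Rcpp::Named("dX") = R_NilValue);
  if (need_dx) {
    fmat Wf = conv_to<fmat>::from(W);
    fmat dXc = dPre * Wf.t();
    fmat dX(static_cast<uword>(n) * L, Cin, fill::zeros);
    for (int j = 0; j < k; ++j) {
      const int shift = j - p;
      const int l0 = std::max(0, -shift);
      const int l1 = std::min(L - 1, L - 1 - shift);
      if (l1 < l0) continue;
      dX.rows(static_cast<uword>(n) * (l0 + shift),
              static_cast<uword>(n) * (l1 + shift + 1) - 1) +=
          dXc.submat(static_cast<uword>(n) * l0, static_cast<uword>(j) * Cin,
                     static_cast<uword>(n) * (l1 + 1) - 1,
                     static_cast<uword>(j) * Cin + Cin - 1);
    }
    out["dX"] = conv_to<mat>::from(dX);
  }
  return out;
}

// Max pooling, factor 2 (L must be even).  Returns pooled batch and a 0/1
// mask marking whether the first element of each pair won (ties -> first).
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::mat& X, int n, int L) {
  const int C = X.n_cols, Lo = L / 2;
  mat Y(static_cast<uword>(n) * Lo, C);
  umat M(static_cast<uword>(n) * Lo, C);
  for (int c = 0; c < C; ++c) {
    for (int l = 0; l < Lo; ++l) {
      const uword ra = static_cast<uword>(n) * (2 * l);
      const uword rb = ra + n;
      const uword ro = static_cast<uword>(n) * l;
      for (int i = 0; i < n; ++i) {
        const double a = X(ra + i, c), b2 = X(rb + i, c);
        const bool first = a >= b2;
        Y(ro + i, c) = first ? a : b2;
        M(ro + i, c) = first ? 1u : 0u;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("mask") = M);
}

// [[Rcpp::export]]
arma::mat maxpool2_bwd(const arma::mat& dY, const arma::umat& M, int n,
                       int Lo) {
  const int C = dY.n_cols;
  mat dX(static_cast<uword>(n) * Lo * 2, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int l = 0; l < Lo; ++l) {
      const uword ra = static_cast<uword>(n) * (2 * l);
      const uword rb = ra + n;
      const uword ro = static_cast<uword>(n) * l;
      for (int i = 0; i < n; ++i) {
        if (M(ro + i, c)) dX(ra + i, c) = dY(ro + i, c);
        else dX(rb + i, c) = dY(ro + i, c);
      }
    }
  }
  return dX;
}

// Nearest-neighbour upsampling, factor 2.
// [[Rcpp::export]]
arma::mat upsample2_fwd(const arma::mat& X, int n, int L) {
  const int C = X.n_cols;
  mat Y(static_cast<uword>(n) * L * 2, C);
  for (int l = 0; l < L; ++l) {
    const uword rs = static_cast<uword>(n) * l;
    const uword ra = static_cast<uword>(n) * (2 * l);
    Y.rows(ra, ra + n - 1) = X.rows(rs, rs + n - 1);
    Y.rows(ra + n, ra + 2 * n - 1) = X.rows(rs, rs + n - 1);
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample2_bwd(const arma::mat& dY, int n, int Lo) {
  const int C = dY.n_cols;
  const int L = Lo / 2;
  mat dX(static_cast<uword>(n) * L, C);
  for (int l = 0; l < L; ++l) {
    const uword rs = static_cast<uword>(n) * l;
    const uword ra = static_cast<uword>(n) * (2 * l);
    dX.rows(rs, rs + n - 1) =
        dY.rows(ra, ra + n - 1) + dY.rows(ra + n, ra + 2 * n - 1);
  }
  return dX;
}
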