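// Compiled numerical core of the compact convolutional network: one fused
// forward+backward training step and an inference-mode forward pass.
// Orchestration (optimiser, shuffling, dropout-mask RNG, batch-norm running
// statistics) stays on the R side so reproducibility is governed entirely by
// R's RNG.  Layouts mirror the R arrays: activations are matrices whose rows
// enumerate (batch x collapsed spatial positions), columns feature maps.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;

static const double BN_EPS = 1e-3;

struct BNCache {
  rowvec mu, var, istd;
  mat xhat;
};

static mat bn_train_fw(const mat& X, const rowvec& g, const rowvec& b,
                       BNCache& c) {
  c.mu = mean(X, 0);
  c.var = mean(square(X), 0) - square(c.mu);
  c.var.transform([](double v) { return v > 0 ? v : 0.0; });
  c.istd = 1.0 / sqrt(c.var + BN_EPS);
  c.xhat = X;
  c.xhat.each_row() -= c.mu;
  c.xhat.each_row() %= c.istd;
  mat y = c.xhat;
  y.each_row() %= g;
  y.each_row() += b;
  return y;
}

static mat bn_infer_fw(const mat& X, const rowvec& g, const rowvec& b,
                       const rowvec& rm, const rowvec& rv) {
  rowvec scale = g / sqrt(rv + BN_EPS);
  mat y = X;
  y.each_row() -= rm;
  y.each_row() %= scale;
  y.each_row() += b;
  return y;
}

// in-place batch-norm backward: dy is overwritten with dx (two passes)
static void bn_bw(mat& dy, const BNCache& c, const rowvec& g,
                  rowvec& dg, rowvec& db) {
  const uword n = dy.n_rows, m = dy.n_cols;
  dg.set_size(m); db.set_size(m);
  for (uword j = 0; j < m; ++j) {
    const double* xh = c.xhat.colptr(j);
    double* d = dy.colptr(j);
    double s1 = 0.0, s2 = 0.0;
    for (uword i = 0; i < n; ++i) { s1 += d[i] * xh[i]; s2 += d[i]; }
    dg[j] = s1; db[j] = s2;
    const double a = g[j] * c.istd[j];
    const double b1 = a * s2 / n, b2 = a * s1 / n;
    for (uword i = 0; i < n; ++i)
      d[i] = a * d[i] - b1 - b2 * xh[i];
  }
}

static void elu_inplace(mat& X) {
  X.transform([](double v) { return v >= 0 ? v : std::expm1(v); });
}

// multiply dy by the ELU gradient, derived from the cached activation
// output a = elu(z): elu'(z) = 1 for a >= 0, a + 1 otherwise
static void elu_grad_mul(mat& dy, const mat& a) {
  const double* ap = a.memptr();
  double* dp = dy.memptr();
  const uword n = dy.n_elem;
  for (uword i = 0; i < n; ++i)
    if (ap[i] < 0) dp[i] *= ap[i] + 1.0;
}

struct Dims {
  int N, C, T, L1, F1, D, M, F2, L2, P1, P2, T1, T2, nb;
};

static Dims get_dims(const List& cfg, int N) {
  Dims d;
  d.N = N;
  d.C = cfg["chans"];
  d.T = cfg["samples"];
  d.L1 = cfg["kern_length"];
  d.F1 = cfg["F1"];
  d.D = cfg["D"];
  d.M = cfg["M"];
  d.F2 = cfg["F2"];
  d.L2 = cfg["sep_kern_length"];
  d.P1 = cfg["pool1"];
  d.P2 = cfg["pool2"];
  d.T1 = cfg["T1"];
  d.T2 = cfg["T2"];
  d.nb = cfg["nb_classes"];
  return d;
}

static mat as_mat(const List& p, const char* nm) {
  NumericVector v = p[nm];
  Rcpp::IntegerVector dm = v.attr("dim");
  return mat(v.begin(), dm[0], dm[1]);  // copy
}
static rowvec as_rowvec(const List& p, const char* nm) {
  NumericVector v = p[nm];
  return rowvec(v.begin(), v.size());
}

// temporal "same"-padded im2col convolution input, shared by fw and bw
static mat build_xcol(const mat& Xm, int T, int L) {
  int pl = (L - 1) / 2;
  mat Xp(Xm.n_rows, T + L - 1, fill::zeros);
  Xp.cols(pl, pl + T - 1) = Xm;
  mat Xcol(Xm.n_rows * T, L);
  for (int l = 0; l < L; ++l)
    Xcol.col(l) = vectorise(Xp.cols(l, l + T - 1));
  return Xcol;
}

// average-pool each column (viewed as N x T) down to N x Tp groups of P
static mat pool_fw(const mat& A, int N, int T, int P, int Tp) {
  mat out(N * Tp, A.n_cols);
  for (uword m = 0; m < A.n_cols; ++m) {
    const mat Am(const_cast<double*>(A.colptr(m)), N, T, false);
    mat Om(out.colptr(m), N, Tp, false, true);
    for (int g = 0; g < Tp; ++g)
      Om.col(g) = mean(Am.cols(g * P, g * P + P - 1), 1);
  }
  return out;
}

static mat pool_bw(const mat& dP, int N, int T, int P, int Tp) {
  mat out(N * T, dP.n_cols, fill::zeros);
  for (uword m = 0; m < dP.n_cols; ++m) {
    const mat dPm(const_cast<double*>(dP.colptr(m)), N, Tp, false);
    mat Om(out.colptr(m), N, T, false, true);
    for (int g = 0; g < Tp; ++g)
      for (int j = 0; j < P; ++j)
        Om.col(g * P + j) = dPm.col(g) / P;
  }
  return out;
}

// permute one temporal-filter map from (N, C, T) storage to (N*T, C)
static mat permute_NCt(const mat& Acol, int N, int C, int T) {
  // Acol is the (N*C, T) view of one map
  mat out(N * T, C);
  for (int c = 0; c < C; ++c) {
    const mat sub = Acol.rows(c * N, c * N + N - 1);   // (N, T)
    out.col(c) = vectorise(sub);
  }
  return out;
}

// scatter back from (N*T, C) to (N*C, T)
static mat unpermute_NCt(const mat& P, int N, int C, int T) {
  mat out(N * C, T);
  for (int c = 0; c < C; ++c) {
    mat sub(N, T);
    sub = reshape(P.col(c), N, T);
    out.rows(c * N, c * N + N - 1) = sub;
  }
  return out;
}

// [[Rcpp::export(name = ".eegnet_step_cpp")]]
List eegnet_step_cpp(List params, List cfg, NumericVector x,
                     const arma::mat& Y, SEXP mask1_, SEXP mask2_) {
  Rcpp::IntegerVector xd = x.attr("dim");
  Dims d = get_dims(cfg, xd[0]);
  const int N = d.N;
  mat Xm(x.begin(), N * d.C, d.T, false);

  mat W1 = as_mat(params, "W1");
  NumericVector W2v = params["W2"];       // (F1, D, C)
  mat Wd = as_mat(params, "Wd");
  mat Wp = as_mat(params, "Wp");
  mat W6 = as_mat(params, "W6");
  rowvec b6 = as_rowvec(params, "b6");
  rowvec g1 = as_rowvec(params, "g1"), be1 = as_rowvec(params, "be1");
  rowvec g2 = as_rowvec(params, "g2"), be2 = as_rowvec(params, "be2");
  rowvec g3 = as_rowvec(params, "g3"), be3 = as_rowvec(params, "be3");

  // ---- forward ----
  mat Xcol = build_xcol(Xm, d.T, d.L1);
  mat Z1 = Xcol * W1.t();                          // (N*C*T, F1)
  BNCache c1;
  mat A1 = bn_train_fw(Z1, g1, be1, c1);

  mat Z2(N * d.T, d.M);
  std::vector<mat> Pf(d.F1);
  for (int f = 0; f < d.F1; ++f) {
    const mat Af(const_cast<double*>(A1.colptr(f)), N * d.C, d.T, false);
    Pf[f] = permute_NCt(Af, N, d.C, d.T);          // (N*T, C)
    mat W2f(d.D, d.C);
    for (int dd = 0; dd < d.D; ++dd)
      for (int c = 0; c < d.C; ++c)
        W2f(dd, c) = W2v[f + d.F1 * (dd + d.D * c)];
    Z2.cols(f * d.D, f * d.D + d.D - 1) = Pf[f] * W2f.t();
  }
  BNCache c2;
  mat A2 = bn_train_fw(Z2, g2, be2, c2);
  elu_inplace(A2);
  mat Pool1 = pool_fw(A2, N, d.T, d.P1, d.T1);     // (N*T1, M)
  if (mask1_ != R_NilValue) {
    NumericVector m1(mask1_);
    mat Mv(m1.begin(), N * d.T1, d.M, false);
    Pool1 %= Mv;
  }
  // separable depthwise along time
  int pl2 = (d.L2 - 1) / 2;
  mat Dpad(N * (d.T1 + d.L2 - 1), d.M, fill::zeros);
  for (int m = 0; m < d.M; ++m) {
    mat Dm(Dpad.colptr(m), N, d.T1 + d.L2 - 1, false, true);
    const mat Pm(const_cast<double*>(Pool1.colptr(m)), N, d.T1, false);
    Dm.cols(pl2, pl2 + d.T1 - 1) = Pm;
  }
  mat Zd(N * d.T1, d.M, fill::zeros);
  for (int m = 0; m < d.M; ++m) {
    const mat Dm(const_cast<double*>(Dpad.colptr(m)), N,
                 d.T1 + d.L2 - 1, false);
    mat Zm(Zd.colptr(m), N, d.T1, false, true);
    for (int l = 0; l < d.L2; ++l)
      Zm += Wd(m, l) * Dm.cols(l, l + d.T1 - 1);
  }
  mat Z3 = Zd * Wp.t();                            // (N*T1, F2)
  BNCache c3;
  mat A3 = bn_train_fw(Z3, g3, be3, c3);
  elu_inplace(A3);
  mat Pool2 = pool_fw(A3, N, d.T1, d.P2, d.T2);    // (N*T2, F2)
  if (mask2_ != R_NilValue) {
    NumericVector m2(mask2_);
    mat Mv(m2.begin(), N * d.T2, d.F2, false);
    Pool2 %= Mv;
  }
  const mat Fl(const_cast<double*>(Pool2.memptr()), N, d.T2 * d.F2, false);
  mat logits = Fl * W6.t();
  logits.each_row() += b6;
  mat P = logits;
  P.each_col() -= max(logits, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);

  // loss and hit count
  double loss = 0.0;
  int hits = 0;
  for (int n = 0; n < N; ++n) {
    uword yc = index_max(Y.row(n));
    double p = P(n, yc);
    loss += -std::log(p > 1e-12 ? p : 1e-12);
    if (index_max(P.row(n)) == yc) ++hits;
  }
  loss /= N;

  // ---- backward ----
  mat dlog = (P - Y) / N;
  mat gW6 = dlog.t() * Fl;
  rowvec gb6 = sum(dlog, 0);
  mat dFl = dlog * W6;                             // (N, T2*F2)
  mat dPool2(dFl.memptr(), N * d.T2, d.F2, false);
  if (mask2_ != R_NilValue) {
    NumericVector m2(mask2_);
    mat Mv(m2.begin(), N * d.T2, d.F2, false);
    dPool2 %= Mv;
  }
  mat dA3 = pool_bw(dPool2, N, d.T1, d.P2, d.T2);
  elu_grad_mul(dA3, A3);
  rowvec gg3, gbe3;
  bn_bw(dA3, c3, g3, gg3, gbe3);                   // dA3 becomes dZ3
  mat gWp = dA3.t() * Zd;
  mat dZd = dA3 * Wp;                              // (N*T1, M)

  mat gWd(d.M, d.L2, fill::zeros);
  mat dDpad(N * (d.T1 + d.L2 - 1), d.M, fill::zeros);
  for (int m = 0; m < d.M; ++m) {
    const mat Dm(const_cast<double*>(Dpad.colptr(m)), N,
                 d.T1 + d.L2 - 1, false);
    const mat dZm(const_cast<double*>(dZd.colptr(m)), N, d.T1, false);
    mat dDm(dDpad.colptr(m), N, d.T1 + d.L2 - 1, false, true);
    for (int l = 0; l < d.L2; ++l) {
      gWd(m, l) = accu(dZm % Dm.cols(l, l + d.T1 - 1));
      dDm.cols(l, l + d.T1 - 1) += Wd(m, l) * dZm;
    }
  }
  mat dPool1(N * d.T1, d.M);
  for (int m = 0; m < d.M; ++m) {
    const mat dDm(const_cast<double*>(dDpad.colptr(m)), N,
                  d.T1 + d.L2 - 1, false);
    mat dPm(dPool1.colptr(m), N, d.T1, false, true);
    dPm = dDm.cols(pl2, pl2 + d.T1 - 1);
  }
  if (mask1_ != R_NilValue) {
    NumericVector m1(mask1_);
    mat Mv(m1.begin(), N * d.T1, d.M, false);
    dPool1 %= Mv;
  }
  mat dA2 = pool_bw(dPool1, N, d.T, d.P1, d.T1);
  elu_grad_mul(dA2, A2);
  rowvec gg2, gbe2;
  bn_bw(dA2, c2, g2, gg2, gbe2);                   // dA2 becomes dZ2
  const mat& dZ2 = dA2;

  NumericVector gW2(d.F1 * d.D * d.C);
  mat dA1(N * d.C * d.T, d.F1);
  for (int f = 0; f < d.F1; ++f) {
    mat dZf = dZ2.cols(f * d.D, f * d.D + d.D - 1); // (N*T, D)
    mat gW2f = dZf.t() * Pf[f];                     // (D, C)
    for (int dd = 0; dd < d.D; ++dd)
      for (int c = 0; c < d.C; ++c)
        gW2[f + d.F1 * (dd + d.D * c)] = gW2f(dd, c);
    mat W2f(d.D, d.C);
    for (int dd = 0; dd < d.D; ++dd)
      for (int c = 0; c < d.C; ++c)
        W2f(dd, c) = W2v[f + d.F1 * (dd + d.D * c)];
    mat dPf = dZf * W2f;                            // (N*T, C)
    dA1.col(f) = vectorise(unpermute_NCt(dPf, N, d.C, d.T));
  }
  rowvec gg1, gbe1;
  bn_bw(dA1, c1, g1, gg1, gbe1);                   // dA1 becomes dZ1
  mat gW1 = dA1.t() * Xcol;                         // (F1, L1)

  gW2.attr("dim") = Rcpp::IntegerVector::create(d.F1, d.D, d.C);
  List grads = List::create(
    Named("W1") = gW1, Named("g1") = gg1, Named("be1") = gbe1,
    Named("W2") = gW2, Named("g2") = gg2, Named("be2") = gbe2,
    Named("Wd") = gWd, Named("Wp") = gWp,
    Named("g3") = gg3, Named("be3") = gbe3,
    Named("W6") = gW6, Named("b6") = gb6);
  List bn = List::create(
    Named("m1") = c1.mu, Named("v1") = c1.var,
    Named("m2") = c2.mu, Named("v2") = c2.var,
    Named("m3") = c3.mu, Named("v3") = c3.var);
  return List::create(Named("grads") = grads, Named("loss") = loss,
                      Named("hits") = hits, Named("bn_batch") = bn);
}

// [[Rcpp::export(name = ".eegnet_infer_cpp")]]
arma::mat eegnet_infer_cpp(List params, List cfg, NumericVector x) {
  Rcpp::IntegerVector xd = x.attr("dim");
  Dims d = get_dims(cfg, xd[0]);
  const int N = d.N;
  mat Xm(x.begin(), N * d.C, d.T, false);

  mat W1 = as_mat(params, "W1");
  NumericVector W2v = params["W2"];
  mat Wd = as_mat(params, "Wd");
  mat Wp = as_mat(params, "Wp");
  mat W6 = as_mat(params, "W6");
  rowvec b6 = as_rowvec(params, "b6");

  mat Xcol = build_xcol(Xm, d.T, d.L1);
  mat Z1 = Xcol * W1.t();
  mat A1 = bn_infer_fw(Z1, as_rowvec(params, "g1"),
                       as_rowvec(params, "be1"),
                       as_rowvec(params, "rm1"), as_rowvec(params, "rv1"));
  mat Z2(N * d.T, d.M);
  for (int f = 0; f < d.F1; ++f) {
    const mat Af(const_cast<double*>(A1.colptr(f)), N * d.C, d.T, false);
    mat Pfm = permute_NCt(Af, N, d.C, d.T);
    mat W2f(d.D, d.C);
    for (int dd = 0; dd < d.D; ++dd)
      for (int c = 0; c < d.C; ++c)
        W2f(dd, c) = W2v[f + d.F1 * (dd + d.D * c)];
    Z2.cols(f * d.D, f * d.D + d.D - 1) = Pfm * W2f.t();
  }
  mat A2 = bn_infer_fw(Z2, as_rowvec(params, "g2"),
                       as_rowvec(params, "be2"),
                       as_rowvec(params, "rm2"), as_rowvec(params, "rv2"));
  elu_inplace(A2);
  mat Pool1 = pool_fw(A2, N, d.T, d.P1, d.T1);
  int pl2 = (d.L2 - 1) / 2;
  mat Zd(N * d.T1, d.M, fill::zeros);
  for (int m = 0; m < d.M; ++m) {
    mat Dm(N, d.T1 + d.L2 - 1, fill::zeros);
    const mat Pm(const_cast<double*>(Pool1.colptr(m)), N, d.T1, false);
    Dm.cols(pl2, pl2 + d.T1 - 1) = Pm;
    mat Zm(Zd.colptr(m), N, d.T1, false, true);
    for (int l = 0; l < d.L2; ++l)
      Zm += Wd(m, l) * Dm.cols(l, l + d.T1 - 1);
  }
  mat Z3 = Zd * Wp.t();
  mat A3 = bn_infer_fw(Z3, as_rowvec(params, "g3"),
                       as_rowvec(params, "be3"),
                       as_rowvec(params, "rm3"), as_rowvec(params, "rv3"));
  elu_inplace(A3);
  mat Pool2 = pool_fw(A3, N, d.T1, d.P2, d.T2);
  const mat Fl(const_cast<double*>(Pool2.memptr()), N, d.T2 * d.F2, false);
  mat logits = Fl * W6.t();
  logits.each_row() += b6;
  mat P = logits;
  P.each_col() -= max(logits, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  return P;
}
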