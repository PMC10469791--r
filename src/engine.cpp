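// Compute kernels for the model engine: banded (local/global) scaled
// dot-product attention and same-padded 1-D convolution, each with an
// analytic backward pass. Token matrices are (T * n_seq) x d with row index
// r = s*T + t (position t fastest within sequence s); feature maps are
// cubes (T, channels, batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Banded self-attention forward. Q,K: (T*S) x d_k, V: (T*S) x d_v.
// Query t attends to keys j with |t - j| <= half (half >= T-1 gives the
// global pattern). Returns the mixed values and the attention probabilities
// P (window x T x S cube, zero outside the valid band).
// [[Rcpp::export]]
Rcpp::List band_attn_fwd(const arma::mat& Q, const arma::mat& K,
                         const arma::mat& V, int T, int half) {
  const int S = Q.n_rows / T;
  const int dk = Q.n_cols, dv = V.n_cols;
  const double scale = 1.0 / std::sqrt((double) dk);
  const int w = 2 * half + 1;
  // transpose once so per-token vectors are contiguous columns
  const mat Qt = Q.t(), Kt = K.t(), Vt = V.t();
  mat outT(dv, V.n_rows);
  cube P(w, T, S, fill::zeros);
  std::vector<double> e(w);
  for (int s = 0; s < S; ++s) {
    const int base = s * T;
    for (int t = 0; t < T; ++t) {
      const int j0 = std::max(0, t - half), j1 = std::min(T - 1, t + half);
      const int L = j1 - j0 + 1;
      const double* q = Qt.colptr(base + t);
      double emax = -1e300;
      for (int j = 0; j < L; ++j) {
        const double* k = Kt.colptr(base + j0 + j);
        double acc = 0.0;
        for (int c = 0; c < dk; ++c) acc += q[c] * k[c];
        e[j] = acc * scale;
        if (e[j] > emax) emax = e[j];
      }
      double esum = 0.0;
      for (int j = 0; j < L; ++j) { e[j] = std::exp(e[j] - emax); esum += e[j]; }
      double* o = outT.colptr(base + t);
      for (int c = 0; c < dv; ++c) o[c] = 0.0;
      for (int j = 0; j < L; ++j) {
        const double p = e[j] / esum;
        P(j0 + j - (t - half), t, s) = p;
        const double* v = Vt.colptr(base + j0 + j);
        for (int c = 0; c < dv; ++c) o[c] += p * v[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = outT.t(),
                            Rcpp::Named("P") = P);
}

// Backward pass of band_attn_fwd given upstream gradient dOut.
// [[Rcpp::export]]
Rcpp::List band_attn_bwd(const arma::mat& dOut, const arma::mat& Q,
                         const arma::mat& K, const arma::mat& V,
                         const arma::cube& P, int T, int half) {
  const int S = Q.n_rows / T;
  const int dk = Q.n_cols, dv = V.n_cols;
  const double scale = 1.0 / std::sqrt((double) dk);
  const mat Qt = Q.t(), Kt = K.t(), Vt = V.t(), Gt = dOut.t();
  mat dQt(dk, Q.n_rows, fill::zeros);
  mat dKt(dk, K.n_rows, fill::zeros);
  mat dVt(dv, V.n_rows, fill::zeros);
  const int w = 2 * half + 1;
  std::vector<double> p(w), dp(w);
  for (int s = 0; s < S; ++s) {
    const int base = s * T;
    for (int t = 0; t < T; ++t) {
      const int j0 = std::max(0, t - half), j1 = std::min(T - 1, t + half);
      const int L = j1 - j0 + 1;
      const double* g = Gt.colptr(base + t);
      double pdp = 0.0;
      for (int j = 0; j < L; ++j) {
        p[j] = P(j0 + j - (t - half), t, s);
        const double* v = Vt.colptr(base + j0 + j);
        double* dvp = dVt.colptr(base + j0 + j);
        double acc = 0.0;
        for (int c = 0; c < dv; ++c) {
          acc += v[c] * g[c];
          dvp[c] += p[j] * g[c];
        }
        dp[j] = acc;
        pdp += p[j] * acc;
      }
      const double* q = Qt.colptr(base + t);
      double* dq = dQt.colptr(base + t);
      for (int j = 0; j < L; ++j) {
        const double de = p[j] * (dp[j] - pdp) * scale;
        const double* k = Kt.colptr(base + j0 + j);
        double* dkp = dKt.colptr(base + j0 + j);
        for (int c = 0; c < dk; ++c) {
          dq[c] += de * k[c];
          dkp[c] += de * q[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQt.t(),
                            Rcpp::Named("dK") = dKt.t(),
                            Rcpp::Named("dV") = dVt.t());
}

// Same-padded 1-D convolution over the first (time) axis.
// X: (T, Cin, N), W: (Klen, Cin, Cout) with odd Klen, b: Cout.
// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::cube& W,
                      const arma::vec& b) {
  const int T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const int Klen = W.n_rows, Cout = W.n_slices;
  const int pad = (Klen - 1) / 2;
  cube Y(T, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      vec acc(T, fill::value(b(o)));
      for (int c = 0; c < Cin; ++c) {
        const vec x = X.slice(n).col(c);
        for (int k = 0; k < Klen; ++k) {
          const double wk = W(k, c, o);
          if (wk == 0.0) continue;
          const int d = k - pad;  // y[t] += wk * x[t + d]
          const int t0 = std::max(0, -d), t1 = std::min(T - 1, T - 1 - d);
          if (t0 > t1) continue;
          acc.subvec(t0, t1) += wk * x.subvec(t0 + d, t1 + d);
        }
      }
      Y.slice(n).col(o) = acc;
    }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& dY, const arma::cube& X,
                      const arma::cube& W) {
  const int T = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const int Klen = W.n_rows, Cout = W.n_slices;
  const int pad = (Klen - 1) / 2;
  cube dX(T, Cin, N, fill::zeros);
  cube dW(Klen, Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const vec g = dY.slice(n).col(o);
      db(o) += accu(g);
      for (int c = 0; c < Cin; ++c) {
        const vec x = X.slice(n).col(c);
        vec dx(T, fill::zeros);
        for (int k = 0; k < Klen; ++k) {
          const int d = k - pad;
          const int t0 = std::max(0, -d), t1 = std::min(T - 1, T - 1 - d);
          if (t0 > t1) continue;
          dW(k, c, o) += dot(g.subvec(t0, t1), x.subvec(t0 + d, t1 + d));
          dx.subvec(t0 + d, t1 + d) += W(k, c, o) * g.subvec(t0, t1);
        }
        dX.slice(n).col(c) += dx;
      }
    }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Average pooling over time: windows of length L starting every `stride`
// samples. X: (T, C, N) -> (T1, C, N) with T1 = floor((T - L)/stride) + 1.
// [[Rcpp::export]]
arma::cube avgpool_fwd(const arma::cube& X, int L, int stride) {
  const int T = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int T1 = (T - L) / stride + 1;
  cube Y(T1, C, N);
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < T1; ++i)
      Y.slice(n).row(i) =
        mean(X.slice(n).rows(i * stride, i * stride + L - 1), 0);
  return Y;
}

// [[Rcpp::export]]
arma::cube avgpool_bwd(const arma::cube& dY, int T, int L, int stride) {
  const int T1 = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  cube dX(T, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < T1; ++i)
      dX.slice(n).rows(i * stride, i * stride + L - 1) +=
        repmat(dY.slice(n).row(i) / L, L, 1);
  return dX;
}

// Multi-head banded self-attention: head loop kept native to avoid
// column-slice copies. Qm,Km: (T*S) x (h*dk), Vm: (T*S) x (h*dv).
// P is (w, T, S*h) with head-major slice blocks (head h slices first... see R).
// [[Rcpp::export]]
Rcpp::List mh_attn_fwd(const arma::mat& Qm, const arma::mat& Km,
                       const arma::mat& Vm, int T, int half, int n_heads) {
  const int dk = Qm.n_cols / n_heads, dv = Vm.n_cols / n_heads;
  const int S = Qm.n_rows / T;
  const double scale = 1.0 / std::sqrt((double) dk);
  const int w = 2 * half + 1;
  const mat Qt = Qm.t(), Kt = Km.t(), Vt = Vm.t();
  mat outT(n_heads * dv, Vm.n_rows);
  cube P(w, T, S * n_heads, fill::zeros);
  std::vector<double> e(w);
  for (int h = 0; h < n_heads; ++h) {
    const int qo = h * dk, vo = h * dv;
    for (int s = 0; s < S; ++s) {
      const int base = s * T;
      double* Pslice = P.slice_memptr(h * S + s);
      for (int t = 0; t < T; ++t) {
        const int j0 = std::max(0, t - half), j1 = std::min(T - 1, t + half);
        const int L = j1 - j0 + 1;
        const double* q = Qt.colptr(base + t) + qo;
        double emax = -1e300;
        for (int j = 0; j < L; ++j) {
          const double* k = Kt.colptr(base + j0 + j) + qo;
          double acc = 0.0;
          for (int c = 0; c < dk; ++c) acc += q[c] * k[c];
          e[j] = acc * scale;
          if (e[j] > emax) emax = e[j];
        }
        double esum = 0.0;
        for (int j = 0; j < L; ++j) {
          e[j] = std::exp(e[j] - emax);
          esum += e[j];
        }
        double* o = outT.colptr(base + t) + vo;
        for (int c = 0; c < dv; ++c) o[c] = 0.0;
        double* Pcol = Pslice + (size_t) t * w;
        for (int j = 0; j < L; ++j) {
          const double p = e[j] / esum;
          Pcol[j0 + j - (t - half)] = p;
          const double* v = Vt.colptr(base + j0 + j) + vo;
          for (int c = 0; c < dv; ++c) o[c] += p * v[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = outT.t(),
                            Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List mh_attn_bwd(const arma::mat& dOut, const arma::mat& Qm,
                       const arma::mat& Km, const arma::mat& Vm,
                       const arma::cube& P, int T, int half, int n_heads) {
  const int dk = Qm.n_cols / n_heads, dv = Vm.n_cols / n_heads;
  const int S = Qm.n_rows / T;
  const double scale = 1.0 / std::sqrt((double) dk);
  const int w = 2 * half + 1;
  const mat Qt = Qm.t(), Kt = Km.t(), Vt = Vm.t(), Gt = dOut.t();
  mat dQt(Qm.n_cols, Qm.n_rows, fill::zeros);
  mat dKt(Km.n_cols, Km.n_rows, fill::zeros);
  mat dVt(Vm.n_cols, Vm.n_rows, fill::zeros);
  std::vector<double> p(w), dp(w);
  for (int h = 0; h < n_heads; ++h) {
    const int qo = h * dk, vo = h * dv;
    for (int s = 0; s < S; ++s) {
      const int base = s * T;
      const double* Pslice = P.slice_memptr(h * S + s);
      for (int t = 0; t < T; ++t) {
        const int j0 = std::max(0, t - half), j1 = std::min(T - 1, t + half);
        const int L = j1 - j0 + 1;
        const double* g = Gt.colptr(base + t) + vo;
        const double* Pcol = Pslice + (size_t) t * w;
        double pdp = 0.0;
        for (int j = 0; j < L; ++j) {
          p[j] = Pcol[j0 + j - (t - half)];
          const double* v = Vt.colptr(base + j0 + j) + vo;
          double* dvp = dVt.colptr(base + j0 + j) + vo;
          double acc = 0.0;
          for (int c = 0; c < dv; ++c) {
            acc += v[c] * g[c];
            dvp[c] += p[j] * g[c];
          }
          dp[j] = acc;
          pdp += p[j] * acc;
        }
        const double* q = Qt.colptr(base + t) + qo;
        double* dq = dQt.colptr(base + t) + qo;
        for (int j = 0; j < L; ++j) {
          const double de = p[j] * (dp[j] - pdp) * scale;
          const double* k = Kt.colptr(base + j0 + j) + qo;
          double* dkp = dKt.colptr(base + j0 + j) + qo;
          for (int c = 0; c < dk; ++c) {
            dq[c] += de * k[c];
            dkp[c] += de * q[c];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQt.t(),
                            Rcpp::Named("dK") = dKt.t(),
                            Rcpp::Named("dV") = dVt.t());
}

// fused elementwise kernels for the large token matrices
// [[Rcpp::export]]
arma::mat elu_fwd_cpp(const arma::mat& X) {
  mat out(X.n_rows, X.n_cols);
  const double* x = X.memptr();
  double* o = out.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) o[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return out;
}

// [[Rcpp::export]]
arma::mat elu_bwd_cpp(const arma::mat& dOut, const arma::mat& X,
                      const arma::mat& Out) {
  mat g(dOut.n_rows, dOut.n_cols);
  const double* d = dOut.memptr();
  const double* x = X.memptr();
  const double* o = Out.memptr();
  double* gp = g.memptr();
  const size_t n = dOut.n_elem;
  for (size_t i = 0; i < n; ++i) gp[i] = x[i] > 0 ? d[i] : d[i] * (o[i] + 1.0);
  return g;
}

// row-wise layer normalization, fused
// [[Rcpp::export]]
Rcpp::List ln_fwd_cpp(const arma::mat& X, const arma::vec& g,
                      const arma::vec& b, double eps) {
  const int n = X.n_rows, d = X.n_cols;
  mat xhat(n, d), out(n, d);
  vec istd(n);
  for (int i = 0; i < n; ++i) {
    double mu = 0.0;
    for (int c = 0; c < d; ++c) mu += X(i, c);
    mu /= d;
    double v = 0.0;
    for (int c = 0; c < d; ++c) {
      const double xc = X(i, c) - mu;
      v += xc * xc;
    }
    v /= d;
    const double is = 1.0 / std::sqrt(v + eps);
    istd(i) = is;
    for (int c = 0; c < d; ++c) {
      const double xh = (X(i, c) - mu) * is;
      xhat(i, c) = xh;
      out(i, c) = xh * g(c) + b(c);
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List ln_bwd_cpp(const arma::mat& dOut, const arma::mat& xhat,
                      const arma::vec& istd, const arma::vec& g) {
  const int n = dOut.n_rows, d = dOut.n_cols;
  mat dX(n, d);
  vec dg(d, fill::zeros), db(d, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double m1 = 0.0, m2 = 0.0;
    for (int c = 0; c < d; ++c) {
      const double dxh = dOut(i, c) * g(c);
      m1 += dxh;
      m2 += dxh * xhat(i, c);
      dg(c) += dOut(i, c) * xhat(i, c);
      db(c) += dOut(i, c);
    }
    m1 /= d;
    m2 /= d;
    for (int c = 0; c < d; ++c)
      dX(i, c) = istd(i) * (dOut(i, c) * g(c) - m1 - xhat(i, c) * m2);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dg") = dg,
                            Rcpp::Named("db") = db);
}

// shape-agnostic ELU kernels (dim attribute restored on the R side)
// [[Rcpp::export]]
Rcpp::NumericVector elu_fwd_vec(const Rcpp::NumericVector& x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector elu_bwd_vec(const Rcpp::NumericVector& d,
                                const Rcpp::NumericVector& x,
                                const Rcpp::NumericVector& out) {
  Rcpp::NumericVector g(d.size());
  for (R_xlen_t i = 0; i < d.size(); ++i)
    g[i] = x[i] > 0 ? d[i] : d[i] * (out[i] + 1.0);
  return g;
}
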