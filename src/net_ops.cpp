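// Numerical kernels for the temporal CNN. Activations use a channels-first
// layout throughout: a batch is a (C x L*B) matrix whose column l + L*s
// holds the feature vector at position l of sample s. This keeps
// convolution (im2col + GEMM), batch normalization and max pooling free of
// R-side array permutations.
//
// Convolutions dominate the arithmetic and can run in single precision
// (the customary choice for CNN training); `single = false` switches to
// double, which the finite-difference gradient tests use.

#include <RcppArmadillo.h>
using namespace arma;

// Gather the im2col matrix of one sample: X2 is (K*Cin x Lo), column l
// holding the receptive field of output position l, rows ordered c*K + k
// to match the weight matrix rows.
template <typename T>
static void gather_im2col(const mat& M, int L, int s, int K, int pad,
                          Mat<T>& X2) {
  const int Cin = M.n_rows;
  const int Lo = L + 2 * pad - K + 1;
  X2.zeros(K * Cin, Lo);
  for (int l = 0; l < Lo; ++l) {
    const int in0 = l - pad;
    T* col = X2.colptr(l);
    for (int k = 0; k < K; ++k) {
      const int li = in0 + k;
      if (li < 0 || li >= L) continue;
      const double* src = M.colptr(L * s + li);
      for (int c = 0; c < Cin; ++c) col[c * K + k] = (T)src[c];
    }
  }
}

template <typename T>
static mat conv_fwd_impl(const mat& M, int L, int B, const mat& w,
                         const vec& b, int K, int pad, bool relu) {
  const int Lo = L + 2 * pad - K + 1;
  const int Cout = w.n_cols;
  Mat<T> Wt = conv_to<Mat<T>>::from(w.t());
  Col<T> bb = conv_to<Col<T>>::from(b);
  mat out(Cout, Lo * B);
  Mat<T> X2, Y;
  for (int s = 0; s < B; ++s) {
    gather_im2col<T>(M, L, s, K, pad, X2);
    Y = Wt * X2;
    Y.each_col() += bb;
    if (relu) Y.transform([](T v) { return v > 0 ? v : (T)0; });
    for (int l = 0; l < Lo; ++l) {
      double* dst = out.colptr(Lo * s + l);
      const T* src = Y.colptr(l);
      for (int c = 0; c < Cout; ++c) dst[c] = (double)src[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& M, int L, int B, const arma::mat& w,
                     const arma::vec& b, int K, int pad,
                     bool relu = false, bool single = true) {
  if ((int)w.n_rows != K * (int)M.n_rows)
    Rcpp::stop("conv1d_fwd: weight rows (%d) != K * Cin (%d)",
               (int)w.n_rows, K * (int)M.n_rows);
  if ((int)M.n_cols != L * B)
    Rcpp::stop("conv1d_fwd: input has %d columns, expected L*B = %d",
               (int)M.n_cols, L * B);
  if (single) return conv_fwd_impl<float>(M, L, B, w, b, K, pad, relu);
  return conv_fwd_impl<double>(M, L, B, w, b, K, pad, relu);
}

template <typename T>
static Rcpp::List conv_bwd_impl(const mat& M, int L, int B, const mat& w,
                                const mat& Gy, int K, int pad, bool need_gx) {
  const int Cin = M.n_rows;
  const int Lo = L + 2 * pad - K + 1;
  const int Cout = w.n_cols;
  Mat<T> W = conv_to<Mat<T>>::from(w);
  Mat<T> gwt(Cout, K * Cin, fill::zeros);   // accumulate transposed
  Col<T> gb(Cout, fill::zeros);
  mat gx;
  if (need_gx) gx.zeros(Cin, L * B);
  Mat<T> X2, Gys(Cout, Lo), G2;
  for (int s = 0; s < B; ++s) {
    for (int l = 0; l < Lo; ++l) {
      const double* src = Gy.colptr(Lo * s + l);
      T* dst = Gys.colptr(l);
      for (int c = 0; c < Cout; ++c) dst[c] = (T)src[c];
    }
    gather_im2col<T>(M, L, s, K, pad, X2);
    gwt += Gys * X2.t();
    gb += sum(Gys, 1);
    if (need_gx) {
      G2 = W * Gys;                          // (K*Cin x Lo)
      for (int l = 0; l < Lo; ++l) {
        const int in0 = l - pad;
        const T* col = G2.colptr(l);
        for (int k = 0; k < K; ++k) {
          const int li = in0 + k;
          if (li < 0 || li >= L) continue;
          double* dst = gx.colptr(L * s + li);
          for (int c = 0; c < Cin; ++c) dst[c] += (double)col[c * K + k];
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("gw") = conv_to<mat>::from(gwt.t()),
    Rcpp::Named("gb") = conv_to<vec>::from(gb));
  if (need_gx) out["gx"] = gx;
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& M, int L, int B, const arma::mat& w,
                      const arma::mat& Gy, int K, int pad,
                      bool need_gx = true, bool single = true) {
  if (single) return conv_bwd_impl<float>(M, L, B, w, Gy, K, pad, need_gx);
  return conv_bwd_impl<double>(M, L, B, w, Gy, K, pad, need_gx);
}

// [[Rcpp::export]]
Rcpp::List maxpool1d_fwd(const arma::mat& M, int L, int B, int K, int stride) {
  const int C = M.n_rows;
  const int Lo = (L - K) / stride + 1;
  mat y(C, Lo * B);
  Rcpp::IntegerVector idx(C * Lo * B);   // input position (0-based, in-sample)
  for (int s = 0; s < B; ++s)
    for (int l = 0; l < Lo; ++l) {
      const int base = l * stride;
      double* dst = y.colptr(Lo * s + l);
      int* ip = &idx[(long)(Lo * s + l) * C];
      for (int c = 0; c < C; ++c) {
        double best = M(c, L * s + base);
        int bi = base;
        for (int k = 1; k < K; ++k) {
          const double v = M(c, L * s + base + k);
          if (v > best) { best = v; bi = base + k; }
        }
        dst[c] = best;
        ip[c] = bi;
      }
    }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat maxpool1d_bwd(const Rcpp::IntegerVector& idx, const arma::mat& Gy,
                        int Lo, int B, int L) {
  const int C = Gy.n_rows;
  mat gx(C, L * B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int l = 0; l < Lo; ++l) {
      const double* g = Gy.colptr(Lo * s + l);
      const int* ip = &idx[(long)(Lo * s + l) * C];
      for (int c = 0; c < C; ++c) gx(c, L * s + ip[c]) += g[c];
    }
  return gx;
}

// Batch normalization over the (L*B) axis per channel, biased variance.
// Reductions accumulate column by column (memory-sequential in the
// channels-first layout).
// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::mat& M, const arma::vec& g,
                      const arma::vec& b, const arma::vec& run_mean,
                      const arma::vec& run_var, bool training,
                      double momentum = 0.1, double eps = 1e-5) {
  const int C = M.n_rows;
  const int N = M.n_cols;
  if (training) {
    vec s1(C, fill::zeros), s2(C, fill::zeros);
    for (int j = 0; j < N; ++j) {
      const double* col = M.colptr(j);
      for (int c = 0; c < C; ++c) { s1[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    vec mu = s1 / N;
    vec v = s2 / N - square(mu);
    v.transform([](double x) { return x > 0 ? x : 0; });
    vec sd = sqrt(v + eps);
    mat y(C, N);
    for (int j = 0; j < N; ++j) {
      const double* col = M.colptr(j);
      double* yy = y.colptr(j);
      for (int c = 0; c < C; ++c)
        yy[c] = g[c] * (col[c] - mu[c]) / sd[c] + b[c];
    }
    return Rcpp::List::create(
      Rcpp::Named("y") = y, Rcpp::Named("mu") = mu, Rcpp::Named("sd") = sd,
      Rcpp::Named("v") = v,
      Rcpp::Named("run_mean") = (1 - momentum) * run_mean + momentum * mu,
      Rcpp::Named("run_var") = (1 - momentum) * run_var + momentum * v);
  }
  vec sd = sqrt(run_var + eps);
  mat y(C, N);
  for (int j = 0; j < N; ++j) {
    const double* col = M.colptr(j);
    double* yy = y.colptr(j);
    for (int c = 0; c < C; ++c)
      yy[c] = g[c] * (col[c] - run_mean[c]) / sd[c] + b[c];
  }
  return Rcpp::List::create(Rcpp::Named("y") = y);
}

// Backward through batch norm and the preceding ReLU in one pass.
// `A` is the post-ReLU, pre-BN activation saved by the forward pass;
// xhat is recomputed from it, and the returned gradient is already
// masked by the ReLU (zero where A == 0).
// [[Rcpp::export]]
Rcpp::List bn_relu_bwd_cpp(const arma::mat& dY, const arma::mat& A,
                           const arma::vec& mu, const arma::vec& sd,
                           const arma::vec& g) {
  const int C = dY.n_rows;
  const int N = dY.n_cols;
  vec sdy(C, fill::zeros), sdyx(C, fill::zeros);
  for (int j = 0; j < N; ++j) {
    const double* dy = dY.colptr(j);
    const double* a = A.colptr(j);
    for (int c = 0; c < C; ++c) {
      sdy[c] += dy[c];
      sdyx[c] += dy[c] * (a[c] - mu[c]) / sd[c];
    }
  }
  vec m1 = sdy / N, m2 = sdyx / N;
  mat dx(C, N);
  for (int j = 0; j < N; ++j) {
    const double* dy = dY.colptr(j);
    const double* a = A.colptr(j);
    double* d = dx.colptr(j);
    for (int c = 0; c < C; ++c)
      d[c] = a[c] > 0 ?
        g[c] * (dy[c] - m1[c] - (a[c] - mu[c]) / sd[c] * m2[c]) / sd[c] : 0.0;
  }
  return Rcpp::List::create(
    Rcpp::Named("dx") = dx,
    Rcpp::Named("dg") = sdyx, Rcpp::Named("db") = sdy);
}

// [[Rcpp::export]]
arma::vec track_max_rcpp(const arma::vec& d, double m0, double beta) {
  const int n = d.n_elem;
  vec m(n);
  double cur = m0;
  for (int i = 0; i < n; ++i) {
    cur = (1.0 - beta) * cur + beta * d[i];
    if (d[i] > cur) cur = d[i];
    m[i] = cur;
  }
  return m;
}
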