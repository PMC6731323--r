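// Four-layer convolutional classifier: conv(N1,M1) -> ReLU -> conv(N2,M2)
// -> ReLU -> maxpool -> FC(F1) -> ReLU -> FC(F2) -> ReLU -> dropout ->
// FC(K) -> softmax.  Single precision throughout; convolutions are
// im2col + GEMM so the heavy lifting goes through BLAS.
//
// Image layout convention: one image is a C x (H*W) matrix, pixel (x, y)
// (0-based, x rightwards, y downwards) in column y + H*x.  Activation
// matrices stack images as contiguous column blocks, which makes the
// output of one convolution directly consumable by the next im2col.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Arch {
  int H, W, C;              // input geometry
  int N1, M1;               // conv1 kernels / kernel size (stride 1, pad 0 handled generally)
  int S1, P1;
  int N2, M2, S2, P2;       // conv2
  int PK, PS;               // pool kernel / stride
  int F1, F2, K;            // fully connected widths and class count
  int H1, W1, H2, W2, Hp, Wp;
  int A1, A2, Ap, FLAT;
};

static Arch read_arch(const List& a) {
  Arch s;
  s.H = a["H"]; s.W = a["W"]; s.C = a["C"];
  s.N1 = a["N1"]; s.M1 = a["M1"]; s.S1 = a["S1"]; s.P1 = a["P1"];
  s.N2 = a["N2"]; s.M2 = a["M2"]; s.S2 = a["S2"]; s.P2 = a["P2"];
  s.PK = a["PK"]; s.PS = a["PS"];
  s.F1 = a["F1"]; s.F2 = a["F2"]; s.K = a["K"];
  s.H1 = (s.H + 2 * s.P1 - s.M1) / s.S1 + 1;
  s.W1 = (s.W + 2 * s.P1 - s.M1) / s.S1 + 1;
  s.H2 = (s.H1 + 2 * s.P2 - s.M2) / s.S2 + 1;
  s.W2 = (s.W1 + 2 * s.P2 - s.M2) / s.S2 + 1;
  s.Hp = (s.H2 - s.PK) / s.PS + 1;
  s.Wp = (s.W2 - s.PK) / s.PS + 1;
  if (s.H1 <= 0 || s.W1 <= 0 || s.H2 <= 0 || s.W2 <= 0 || s.Hp <= 0 || s.Wp <= 0)
    stop("network architecture yields a non-positive feature-map size");
  s.A1 = s.H1 * s.W1;
  s.A2 = s.H2 * s.W2;
  s.Ap = s.Hp * s.Wp;
  s.FLAT = s.N2 * s.Ap;
  return s;
}

struct Weights {
  fmat W1, W2, W3, W4, W5;
  fvec b1, b2, b3, b4, b5;
};

static fmat as_f(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = out.memptr();
  const R_xlen_t n = (R_xlen_t)m.nrow() * m.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static fvec as_fv(const NumericVector& v) {
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericMatrix as_d(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const R_xlen_t n = (R_xlen_t)m.n_rows * m.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

static NumericVector as_dv(const fvec& v) {
  NumericVector out(v.n_elem);
  for (size_t i = 0; i < v.n_elem; ++i) out[i] = (double)v[i];
  return out;
}

static Weights read_weights(const List& w) {
  Weights W;
  W.W1 = as_f(w["W1"]); W.b1 = as_fv(w["b1"]);
  W.W2 = as_f(w["W2"]); W.b2 = as_fv(w["b2"]);
  W.W3 = as_f(w["W3"]); W.b3 = as_fv(w["b3"]);
  W.W4 = as_f(w["W4"]); W.b4 = as_fv(w["b4"]);
  W.W5 = as_f(w["W5"]); W.b5 = as_fv(w["b5"]);
  return W;
}

// Convert R image array block (H, W, C layout, column-major) to C x (H*W).
static void image_to_cm(const double* src, int H, int W, int C, fmat& dst, int col0) {
  const int HW = H * W;
  for (int px = 0; px < HW; ++px) {
    float* d = dst.colptr(col0 + px);
    for (int c = 0; c < C; ++c) d[c] = (float)src[px + (R_xlen_t)c * HW];
  }
}

// im2col for one image stored as C x (H*W) column block of `X` starting at xcol0.
// Output columns [qcol0, qcol0 + Ho*Wo) of `col`; row index c + C*(dy + M*dx).
static void im2col_one(const fmat& X, int xcol0, int H, int W, int C,
                       int M, int s, int p, int Ho, int Wo,
                       fmat& col, int qcol0) {
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      float* dst = col.colptr(qcol0 + oy + Ho * ox);
      for (int dx = 0; dx < M; ++dx) {
        const int ix = ox * s + dx - p;
        const bool xin = ix >= 0 && ix < W;
        for (int dy = 0; dy < M; ++dy) {
          const int iy = oy * s + dy - p;
          float* d = dst + C * (dy + M * dx);
          if (!xin || iy < 0 || iy >= H) {
            for (int c = 0; c < C; ++c) d[c] = 0.0f;
          } else {
            const float* srcp = X.colptr(xcol0 + iy + H * ix);
            for (int c = 0; c < C; ++c) d[c] = srcp[c];
          }
        }
      }
    }
  }
}

// Scatter-add of dcol back onto dX (reverse of im2col_one).
static void col2im_one(const fmat& dcol, int qcol0, int H, int W, int C,
                       int M, int s, int p, int Ho, int Wo,
                       fmat& dX, int xcol0) {
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      const float* src = dcol.colptr(qcol0 + oy + Ho * ox);
      for (int dx = 0; dx < M; ++dx) {
        const int ix = ox * s + dx - p;
        if (ix < 0 || ix >= W) continue;
        for (int dy = 0; dy < M; ++dy) {
          const int iy = oy * s + dy - p;
          if (iy < 0 || iy >= H) continue;
          const float* sp = src + C * (dy + M * dx);
          float* d = dX.colptr(xcol0 + iy + H * ix);
          for (int c = 0; c < C; ++c) d[c] += sp[c];
        }
      }
    }
  }
}

static inline void relu_(fmat& A) {
  float* p = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero entries of G where the forward activation A was clipped by ReLU
static inline void relu_mask_(fmat& G, const fmat& A) {
  float* g = G.memptr();
  const float* a = A.memptr();
  const size_t n = G.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] == 0.0f) g[i] = 0.0f;
}

// fused momentum update: V = mu V - eta dW; W += V (single pass)
static inline void sgd_(fmat& Wm, fmat& Vm, const fmat& G, float mu, float eta) {
  float* w = Wm.memptr(); float* v = Vm.memptr();
  const float* g = G.memptr();
  const size_t n = Wm.n_elem;
  for (size_t i = 0; i < n; ++i) {
    v[i] = mu * v[i] - eta * g[i];
    w[i] += v[i];
  }
}
static inline void sgd_(fvec& Wm, fvec& Vm, const fvec& G, float mu, float eta) {
  for (size_t i = 0; i < Wm.n_elem; ++i) {
    Vm[i] = mu * Vm[i] - eta * G[i];
    Wm[i] += Vm[i];
  }
}

// Intermediates kept for backprop.
struct Fwd {
  fmat col1, act1, col2, act2, pool, flat, h1, h2, logits, probs;
  arma::Mat<int> poolsrc;   // column index (within act2) of each pooled max
};

// Forward pass over a batch of B images held in `X` (C x B*H*W).
static void forward(const fmat& X, int B, const Arch& s, const Weights& W,
                    Fwd& f, bool keep) {
  f.col1.set_size(s.C * s.M1 * s.M1, (size_t)B * s.A1);
  for (int i = 0; i < B; ++i)
    im2col_one(X, i * s.H * s.W, s.H, s.W, s.C, s.M1, s.S1, s.P1,
               s.H1, s.W1, f.col1, i * s.A1);
  f.act1 = W.W1 * f.col1;
  f.act1.each_col() += W.b1;
  relu_(f.act1);

  f.col2.set_size(s.N1 * s.M2 * s.M2, (size_t)B * s.A2);
  for (int i = 0; i < B; ++i)
    im2col_one(f.act1, i * s.A1, s.H1, s.W1, s.N1, s.M2, s.S2, s.P2,
               s.H2, s.W2, f.col2, i * s.A2);
  f.act2 = W.W2 * f.col2;
  f.act2.each_col() += W.b2;
  relu_(f.act2);

  // max pool (PK x PK, stride PS) per image, per channel
  f.pool.set_size(s.N2, (size_t)B * s.Ap);
  if (keep) f.poolsrc.set_size(s.N2, (size_t)B * s.Ap);
  for (int i = 0; i < B; ++i) {
    const int in0 = i * s.A2, out0 = i * s.Ap;
    for (int ox = 0; ox < s.Wp; ++ox) {
      for (int oy = 0; oy < s.Hp; ++oy) {
        const int q = out0 + oy + s.Hp * ox;
        float* dst = f.pool.colptr(q);
        int* srci = keep ? f.poolsrc.colptr(q) : nullptr;
        bool first = true;
        for (int dx = 0; dx < s.PK; ++dx) {
          const int ix = ox * s.PS + dx;
          if (ix >= s.W2) continue;
          for (int dy = 0; dy < s.PK; ++dy) {
            const int iy = oy * s.PS + dy;
            if (iy >= s.H2) continue;
            const int qc = in0 + iy + s.H2 * ix;
            const float* src = f.act2.colptr(qc);
            if (first) {
              for (int n = 0; n < s.N2; ++n) {
                dst[n] = src[n];
                if (srci) srci[n] = qc;
              }
              first = false;
            } else {
              for (int n = 0; n < s.N2; ++n)
                if (src[n] > dst[n]) {
                  dst[n] = src[n];
                  if (srci) srci[n] = qc;
                }
            }
          }
        }
      }
    }
  }

  // flatten: image i -> column i, element n + N2*q
  f.flat = arma::reshape(f.pool, s.FLAT, B);

  f.h1 = W.W3 * f.flat;
  f.h1.each_col() += W.b3;
  relu_(f.h1);
  f.h2 = W.W4 * f.h1;
  f.h2.each_col() += W.b4;
  relu_(f.h2);
  f.logits = W.W5 * f.h2;   // dropout (train only) applied by caller before this
  f.logits.each_col() += W.b5;

  f.probs = f.logits;
  for (arma::uword j = 0; j < f.probs.n_cols; ++j) {
    fvec c = f.probs.col(j);
    c -= c.max();
    c = arma::exp(c);
    f.probs.col(j) = c / arma::accu(c);
  }
}

// [[Rcpp::export]]
List cnn_forward_cpp(NumericVector X, List weights, List arch) {
  const Arch s = read_arch(arch);
  const Weights W = read_weights(weights);
  IntegerVector dim = X.attr("dim");
  if (dim.size() != 4 || dim[0] != s.H || dim[1] != s.W || dim[2] != s.C)
    stop("patch array must have dimensions H x W x C x n matching the network input");
  const int n = dim[3];
  const int chunk = 50;
  NumericMatrix logits(n, s.K), probs(n, s.K);
  fmat Xf;
  Fwd f;
  for (int at = 0; at < n; at += chunk) {
    const int B = std::min(chunk, n - at);
    Xf.set_size(s.C, (size_t)B * s.H * s.W);
    for (int i = 0; i < B; ++i)
      image_to_cm(X.begin() + (R_xlen_t)(at + i) * s.H * s.W * s.C,
                  s.H, s.W, s.C, Xf, i * s.H * s.W);
    forward(Xf, B, s, W, f, false);
    for (int i = 0; i < B; ++i)
      for (int k = 0; k < s.K; ++k) {
        logits(at + i, k) = f.logits(k, i);
        probs(at + i, k) = f.probs(k, i);
      }
  }
  return List::create(_["logits"] = logits, _["probabilities"] = probs);
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector X, IntegerVector y, List weights, List arch,
                   double lr, double momentum, int epochs, int batch_size,
                   double dropout_rate, int seed) {
  const Arch s = read_arch(arch);
  Weights W = read_weights(weights);
  IntegerVector dim = X.attr("dim");
  if (dim.size() != 4 || dim[0] != s.H || dim[1] != s.W || dim[2] != s.C)
    stop("patch array must have dimensions H x W x C x n matching the network input");
  const int n = dim[3];
  if (n < 1) stop("empty patch set");
  if (epochs < 1) stop("epochs must be >= 1");
  if (batch_size < 1) stop("batch_size must be >= 1");

  // convert every image once
  fmat Xall(s.C, (size_t)n * s.H * s.W);
  for (int i = 0; i < n; ++i)
    image_to_cm(X.begin() + (R_xlen_t)i * s.H * s.W * s.C, s.H, s.W, s.C,
                Xall, i * s.H * s.W);

  Weights V;  // momentum buffers
  V.W1 = arma::zeros<fmat>(arma::size(W.W1)); V.b1 = arma::zeros<fvec>(W.b1.n_elem);
  V.W2 = arma::zeros<fmat>(arma::size(W.W2)); V.b2 = arma::zeros<fvec>(W.b2.n_elem);
  V.W3 = arma::zeros<fmat>(arma::size(W.W3)); V.b3 = arma::zeros<fvec>(W.b3.n_elem);
  V.W4 = arma::zeros<fmat>(arma::size(W.W4)); V.b4 = arma::zeros<fvec>(W.b4.n_elem);
  V.W5 = arma::zeros<fmat>(arma::size(W.W5)); V.b5 = arma::zeros<fvec>(W.b5.n_elem);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const float mu = (float)momentum, eta = (float)lr;
  const float keep = 1.0f - (float)dropout_rate;
  NumericVector ep_loss(epochs), ep_acc(epochs);
  fmat Xb, Y, drop, dZ, dH2, dH1, dF, dpool, dact2, dcol2, dact1;
  // gradient buffers allocated once; per-batch reallocation of the
  // large FC1 gradient would dominate the run time
  fmat dW1(arma::size(W.W1)), dW2(arma::size(W.W2)), dW3(arma::size(W.W3)),
       dW4(arma::size(W.W4)), dW5(arma::size(W.W5));
  fvec db1, db2, db3, db4, db5;
  Fwd f;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    long correct = 0;
    for (int at = 0; at < n; at += batch_size) {
      const int B = std::min(batch_size, n - at);
      Xb.set_size(s.C, (size_t)B * s.H * s.W);
      Y = arma::zeros<fmat>(s.K, B);
      for (int i = 0; i < B; ++i) {
        const int idx = order[at + i];
        Xb.cols(i * s.H * s.W, (i + 1) * s.H * s.W - 1) =
          Xall.cols(idx * s.H * s.W, (idx + 1) * s.H * s.W - 1);
        Y(y[idx], i) = 1.0f;
      }

      // forward up to h2, then dropout, then output layer
      forward(Xb, B, s, W, f, true);
      // redo output with dropout applied (inverted dropout)
      if (keep < 1.0f) {
        drop.set_size(s.F2, B);
        for (arma::uword i = 0; i < drop.n_elem; ++i)
          drop[i] = unif(rng) < keep ? 1.0f / keep : 0.0f;
        f.h2 %= drop;
        f.logits = W.W5 * f.h2;
        f.logits.each_col() += W.b5;
        f.probs = f.logits;
        for (arma::uword j = 0; j < f.probs.n_cols; ++j) {
          fvec c = f.probs.col(j);
          c -= c.max();
          c = arma::exp(c);
          f.probs.col(j) = c / arma::accu(c);
        }
      }

      for (int i = 0; i < B; ++i) {
        const int idx = order[at + i];
        const float p = std::max(f.probs(y[idx], i), 1e-12f);
        loss_sum += -std::log((double)p);
        if ((int)f.probs.col(i).index_max() == y[idx]) ++correct;
      }

      // backward
      dZ = (f.probs - Y) / (float)B;
      dW5 = dZ * f.h2.t();
      db5 = arma::sum(dZ, 1);
      dH2 = W.W5.t() * dZ;
      if (keep < 1.0f) dH2 %= drop;
      relu_mask_(dH2, f.h2);
      dW4 = dH2 * f.h1.t();
      db4 = arma::sum(dH2, 1);
      dH1 = W.W4.t() * dH2;
      relu_mask_(dH1, f.h1);
      dW3 = dH1 * f.flat.t();
      db3 = arma::sum(dH1, 1);
      dF = W.W3.t() * dH1;  // FLAT x B

      // unpool
      dact2 = arma::zeros<fmat>(s.N2, (size_t)B * s.A2);
      {
        const fmat dpoolm = arma::reshape(dF, s.N2, (size_t)B * s.Ap);
        for (arma::uword q = 0; q < dpoolm.n_cols; ++q) {
          const float* src = dpoolm.colptr(q);
          const int* srci = f.poolsrc.colptr(q);
          for (int nch = 0; nch < s.N2; ++nch)
            dact2(nch, srci[nch]) += src[nch];
        }
      }
      relu_mask_(dact2, f.act2);
      dW2 = dact2 * f.col2.t();
      db2 = arma::sum(dact2, 1);
      dcol2 = W.W2.t() * dact2;
      if (dact1.n_rows != (arma::uword)s.N1 ||
          dact1.n_cols != (arma::uword)B * s.A1)
        dact1.set_size(s.N1, (size_t)B * s.A1);
      dact1.zeros();
      for (int i = 0; i < B; ++i)
        col2im_one(dcol2, i * s.A2, s.H1, s.W1, s.N1, s.M2, s.S2, s.P2,
                   s.H2, s.W2, dact1, i * s.A1);
      relu_mask_(dact1, f.act1);
      dW1 = dact1 * f.col1.t();
      db1 = arma::sum(dact1, 1);

      // SGD with momentum
      sgd_(W.W1, V.W1, dW1, mu, eta); sgd_(W.b1, V.b1, db1, mu, eta);
      sgd_(W.W2, V.W2, dW2, mu, eta); sgd_(W.b2, V.b2, db2, mu, eta);
      sgd_(W.W3, V.W3, dW3, mu, eta); sgd_(W.b3, V.b3, db3, mu, eta);
      sgd_(W.W4, V.W4, dW4, mu, eta); sgd_(W.b4, V.b4, db4, mu, eta);
      sgd_(W.W5, V.W5, dW5, mu, eta); sgd_(W.b5, V.b5, db5, mu, eta);

      Rcpp::checkUserInterrupt();
    }
    ep_loss[ep] = loss_sum / n;
    ep_acc[ep] = (double)correct / n;
  }

  List wout = List::create(
    _["W1"] = as_d(W.W1), _["b1"] = as_dv(W.b1),
    _["W2"] = as_d(W.W2), _["b2"] = as_dv(W.b2),
    _["W3"] = as_d(W.W3), _["b3"] = as_dv(W.b3),
    _["W4"] = as_d(W.W4), _["b4"] = as_dv(W.b4),
    _["W5"] = as_d(W.W5), _["b5"] = as_dv(W.b5));
  return List::create(_["weights"] = wout,
                      _["loss"] = ep_loss,
                      _["accuracy"] = ep_acc);
}
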