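// Analytic CNN engine for the drowsecam architecture:
//   BN -> Conv 32@5x5 + LeakyReLU -> BN -> MaxPool(2,2)/2
//      -> Conv 64@3x3 + LeakyReLU -> BN -> MaxPool(2,2)/2
//      -> Flatten -> Dense 512 + LeakyReLU -> BN -> Dense 2 -> SoftMax
// Channel counts are read from the weight arrays, so reduced "toy" models
// (fewer filters / units) run through the same code paths.
//
// Activation layout: matrices with rows = sample-major pixels
// (row = b*H*W + w*H + h, matching R's column-major (h, w) order) and
// columns = channels. Convolutions go through im2col + BLAS gemm.
// The SGD training loop runs in single precision (the usual deep-learning
// arithmetic); inference and the standalone conv2d primitive run in double.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LEAKY_ALPHA = 0.3;

template <typename T>
struct BNParamsT {
  arma::Col<T> gamma, beta, rmean, rvar;
};

template <typename T>
struct ConvParamsT {
  arma::Mat<T> W;       // (k*k*cin) x cout
  arma::Row<T> b;       // cout
  int k = 0, cin = 0, cout = 0;
};

template <typename T>
struct DenseParamsT {
  arma::Mat<T> W;       // in x out
  arma::Row<T> b;
};

template <typename T>
struct CNNWeightsT {
  BNParamsT<T> bn0, bn1, bn2, bn3;
  ConvParamsT<T> conv1, conv2;
  DenseParamsT<T> dense1, dense2;
};

typedef CNNWeightsT<double> CNNWeights;

static BNParamsT<double> parse_bn(const List& l) {
  BNParamsT<double> p;
  p.gamma = as<arma::vec>(l["gamma"]);
  p.beta  = as<arma::vec>(l["beta"]);
  p.rmean = as<arma::vec>(l["mean"]);
  p.rvar  = as<arma::vec>(l["var"]);
  return p;
}

static ConvParamsT<double> parse_conv(const List& l) {
  ConvParamsT<double> p;
  NumericVector W = l["W"];
  IntegerVector d = W.attr("dim");
  if (d.size() != 4 || d[0] != d[1])
    stop("convolution weights must be a (k, k, cin, cout) array");
  p.k = d[0]; p.cin = d[2]; p.cout = d[3];
  p.W = arma::mat(W.begin(), p.k * p.k * p.cin, p.cout);
  p.b = as<arma::rowvec>(l["b"]);
  return p;
}

static DenseParamsT<double> parse_dense(const List& l) {
  DenseParamsT<double> p;
  NumericMatrix W = l["W"];
  p.W = arma::mat(W.begin(), W.nrow(), W.ncol());
  p.b = as<arma::rowvec>(l["b"]);
  return p;
}

static CNNWeights parse_weights(const List& w) {
  CNNWeights cw;
  cw.bn0 = parse_bn(w["bn0"]);
  cw.conv1 = parse_conv(w["conv1"]);
  cw.bn1 = parse_bn(w["bn1"]);
  cw.conv2 = parse_conv(w["conv2"]);
  cw.bn2 = parse_bn(w["bn2"]);
  cw.dense1 = parse_dense(w["dense1"]);
  cw.bn3 = parse_bn(w["bn3"]);
  cw.dense2 = parse_dense(w["dense2"]);
  return cw;
}

template <typename T>
static CNNWeightsT<T> convert_weights(const CNNWeights& w) {
  CNNWeightsT<T> o;
  auto bn = [](const BNParamsT<double>& p) {
    BNParamsT<T> q;
    q.gamma = arma::conv_to<arma::Col<T>>::from(p.gamma);
    q.beta  = arma::conv_to<arma::Col<T>>::from(p.beta);
    q.rmean = arma::conv_to<arma::Col<T>>::from(p.rmean);
    q.rvar  = arma::conv_to<arma::Col<T>>::from(p.rvar);
    return q;
  };
  o.bn0 = bn(w.bn0); o.bn1 = bn(w.bn1); o.bn2 = bn(w.bn2); o.bn3 = bn(w.bn3);
  o.conv1.W = arma::conv_to<arma::Mat<T>>::from(w.conv1.W);
  o.conv1.b = arma::conv_to<arma::Row<T>>::from(w.conv1.b);
  o.conv1.k = w.conv1.k; o.conv1.cin = w.conv1.cin; o.conv1.cout = w.conv1.cout;
  o.conv2.W = arma::conv_to<arma::Mat<T>>::from(w.conv2.W);
  o.conv2.b = arma::conv_to<arma::Row<T>>::from(w.conv2.b);
  o.conv2.k = w.conv2.k; o.conv2.cin = w.conv2.cin; o.conv2.cout = w.conv2.cout;
  o.dense1.W = arma::conv_to<arma::Mat<T>>::from(w.dense1.W);
  o.dense1.b = arma::conv_to<arma::Row<T>>::from(w.dense1.b);
  o.dense2.W = arma::conv_to<arma::Mat<T>>::from(w.dense2.W);
  o.dense2.b = arma::conv_to<arma::Row<T>>::from(w.dense2.b);
  return o;
}

template <typename T>
static List bn_to_list(const BNParamsT<T>& p) {
  arma::vec g = arma::conv_to<arma::vec>::from(p.gamma);
  arma::vec b = arma::conv_to<arma::vec>::from(p.beta);
  arma::vec m = arma::conv_to<arma::vec>::from(p.rmean);
  arma::vec v = arma::conv_to<arma::vec>::from(p.rvar);
  return List::create(_["gamma"] = NumericVector(g.begin(), g.end()),
                      _["beta"]  = NumericVector(b.begin(), b.end()),
                      _["mean"]  = NumericVector(m.begin(), m.end()),
                      _["var"]   = NumericVector(v.begin(), v.end()));
}

template <typename T>
static List conv_to_list(const ConvParamsT<T>& p) {
  arma::mat Wd = arma::conv_to<arma::mat>::from(p.W);
  arma::rowvec bd = arma::conv_to<arma::rowvec>::from(p.b);
  NumericVector W(Wd.begin(), Wd.end());
  W.attr("dim") = IntegerVector::create(p.k, p.k, p.cin, p.cout);
  return List::create(_["W"] = W, _["b"] = NumericVector(bd.begin(), bd.end()));
}

template <typename T>
static List dense_to_list(const DenseParamsT<T>& p) {
  arma::mat Wd = arma::conv_to<arma::mat>::from(p.W);
  arma::rowvec bd = arma::conv_to<arma::rowvec>::from(p.b);
  NumericMatrix W(Wd.n_rows, Wd.n_cols);
  std::memcpy(W.begin(), Wd.memptr(), sizeof(double) * Wd.n_elem);
  return List::create(_["W"] = W, _["b"] = NumericVector(bd.begin(), bd.end()));
}

template <typename T>
static List weights_to_list(const CNNWeightsT<T>& cw, RObject input_shape) {
  List out = List::create(
    _["bn0"] = bn_to_list(cw.bn0),
    _["conv1"] = conv_to_list(cw.conv1),
    _["bn1"] = bn_to_list(cw.bn1),
    _["conv2"] = conv_to_list(cw.conv2),
    _["bn2"] = bn_to_list(cw.bn2),
    _["dense1"] = dense_to_list(cw.dense1),
    _["bn3"] = bn_to_list(cw.bn3),
    _["dense2"] = dense_to_list(cw.dense2));
  out.attr("input_shape") = input_shape;
  return out;
}

// im2col with "same" zero padding, stride 1.
// X: (B*H*W) x Cin, output: (B*H*W) x (k*k*Cin);
// column index = dh + k*dw + k*k*ci, matching R's column-major
// flattening of a (k, k, cin) kernel block.
template <typename T>
static arma::Mat<T> im2col(const arma::Mat<T>& X, int H, int W, int B, int k) {
  const int Cin = X.n_cols, HW = H * W, p = (k - 1) / 2;
  arma::Mat<T> C(X.n_rows, (arma::uword)k * k * Cin, arma::fill::zeros);
  const T* xp = X.memptr();
  T* cp = C.memptr();
  const arma::uword nr = X.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const arma::uword col = (arma::uword)(dh + k * dw) + (arma::uword)k * k * ci;
        const int h_lo = std::max(0, p - dh);
        const int h_hi = std::min(H, H + p - dh);
        const int len = h_hi - h_lo;
        if (len <= 0) continue;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int w_in = w + dw - p;
            if (w_in < 0 || w_in >= W) continue;
            const arma::uword dst = col * nr + (arma::uword)b * HW + (arma::uword)w * H + h_lo;
            const arma::uword src = (arma::uword)ci * nr + (arma::uword)b * HW + (arma::uword)w_in * H + (h_lo + dh - p);
            std::memcpy(cp + dst, xp + src, sizeof(T) * len);
          }
        }
      }
    }
  }
  return C;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
template <typename T>
static arma::Mat<T> col2im(const arma::Mat<T>& dC, int H, int W, int B, int k,
                           int Cin) {
  const int HW = H * W, p = (k - 1) / 2;
  arma::Mat<T> dX(dC.n_rows, Cin, arma::fill::zeros);
  const T* cp = dC.memptr();
  T* xp = dX.memptr();
  const arma::uword nr = dC.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const arma::uword col = (arma::uword)(dh + k * dw) + (arma::uword)k * k * ci;
        const int h_lo = std::max(0, p - dh);
        const int h_hi = std::min(H, H + p - dh);
        const int len = h_hi - h_lo;
        if (len <= 0) continue;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int w_in = w + dw - p;
            if (w_in < 0 || w_in >= W) continue;
            const T* s = cp + col * nr + (arma::uword)b * HW + (arma::uword)w * H + h_lo;
            T* t = xp + (arma::uword)ci * nr + (arma::uword)b * HW + (arma::uword)w_in * H + (h_lo + dh - p);
            for (int i = 0; i < len; ++i) t[i] += s[i];
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 max pooling, stride 2; trailing odd rows/columns are dropped.
template <typename T>
static arma::Mat<T> maxpool_fwd(const arma::Mat<T>& X, int H, int W, int B,
                                arma::umat& idx) {
  const int C = X.n_cols, H2 = H / 2, W2 = W / 2, HW = H * W, HW2 = H2 * W2;
  arma::Mat<T> Y((arma::uword)B * HW2, C);
  idx.set_size((arma::uword)B * HW2, C);
  const T* xp = X.memptr();
  T* yp = Y.memptr();
  arma::uword* ip = idx.memptr();
  for (int c = 0; c < C; ++c) {
    const T* xc = xp + (arma::uword)c * X.n_rows;
    T* yc = yp + (arma::uword)c * Y.n_rows;
    arma::uword* ic = ip + (arma::uword)c * Y.n_rows;
    for (int b = 0; b < B; ++b) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          const arma::uword base = (arma::uword)b * HW + (arma::uword)(2 * w2) * H + 2 * h2;
          arma::uword best = base;
          T bv = xc[base];
          const arma::uword cand[3] = {base + 1, base + H, base + H + 1};
          for (int t = 0; t < 3; ++t) {
            const T v = xc[cand[t]];
            if (v > bv) { bv = v; best = cand[t]; }
          }
          const arma::uword r2 = (arma::uword)b * HW2 + (arma::uword)w2 * H2 + h2;
          yc[r2] = bv;
          ic[r2] = best;
        }
      }
    }
  }
  return Y;
}

template <typename T>
static arma::Mat<T> maxpool_bwd(const arma::Mat<T>& dY, const arma::umat& idx,
                                arma::uword rows_in) {
  arma::Mat<T> dX(rows_in, dY.n_cols, arma::fill::zeros);
  const T* dyp = dY.memptr();
  const arma::uword* ip = idx.memptr();
  T* dxp = dX.memptr();
  for (arma::uword c = 0; c < dY.n_cols; ++c)
    for (arma::uword r = 0; r < dY.n_rows; ++r)
      dxp[c * rows_in + ip[c * dY.n_rows + r]] += dyp[c * dY.n_rows + r];
  return dX;
}

template <typename T>
static inline arma::Mat<T> leaky(const arma::Mat<T>& Z) {
  return arma::max(Z, (T)LEAKY_ALPHA * Z);
}

// multiply dA elementwise by LeakyReLU'(Z) in place
template <typename T>
static inline void leaky_grad_inplace(arma::Mat<T>& dA, const arma::Mat<T>& Z) {
  T* d = dA.memptr();
  const T* z = Z.memptr();
  const T a = (T)LEAKY_ALPHA;
  for (arma::uword i = 0; i < dA.n_elem; ++i)
    if (z[i] < (T)0) d[i] *= a;
}

template <typename T>
struct BNCacheT {
  arma::Mat<T> xhat;
  arma::Row<T> invstd;
};

template <typename T>
static arma::Mat<T> bn_train_fwd(const arma::Mat<T>& X, BNParamsT<T>& p,
                                 T eps, T momentum, BNCacheT<T>& cache) {
  const T Nr = (T)X.n_rows;
  arma::Row<T> mu = arma::mean(X, 0);
  arma::Row<T> var = arma::sum(arma::square(X.each_row() - mu), 0) / Nr; // biased
  cache.invstd = (T)1 / arma::sqrt(var + eps);
  cache.xhat = (X.each_row() - mu).each_row() % cache.invstd;
  p.rmean = momentum * p.rmean + ((T)1 - momentum) * mu.t();
  p.rvar  = momentum * p.rvar  + ((T)1 - momentum) * var.t();
  arma::Mat<T> Y = cache.xhat.each_row() % p.gamma.t();
  Y.each_row() += p.beta.t();
  return Y;
}

template <typename T>
static arma::Mat<T> bn_train_bwd(const arma::Mat<T>& dY,
                                 const BNCacheT<T>& cache,
                                 const BNParamsT<T>& p, arma::Row<T>& dgamma,
                                 arma::Row<T>& dbeta) {
  const T Nr = (T)dY.n_rows;
  dgamma = arma::sum(dY % cache.xhat, 0);
  dbeta = arma::sum(dY, 0);
  arma::Mat<T> dX = Nr * dY;
  dX.each_row() -= dbeta;
  dX -= cache.xhat.each_row() % dgamma;
  dX.each_row() %= (p.gamma.t() % cache.invstd) / Nr;
  return dX;
}

template <typename T>
static arma::Mat<T> bn_infer(const arma::Mat<T>& X, const BNParamsT<T>& p,
                             T eps) {
  arma::Row<T> scale = (p.gamma / arma::sqrt(p.rvar + eps)).t();
  arma::Row<T> shift = (p.beta - p.gamma % p.rmean / arma::sqrt(p.rvar + eps)).t();
  arma::Mat<T> Y = X.each_row() % scale;
  Y.each_row() += shift;
  return Y;
}

// Reshape an R (H, W, C, N) image array into the engine's pixel-major matrix.
template <typename T>
static arma::Mat<T> array_to_mat(const NumericVector& x, int& H, int& W,
                                 int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("image batch must be a (H, W, C, N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
  const int HW = H * W;
  arma::Mat<T> X((arma::uword)N * HW, C);
  const double* src = x.begin();
  T* dst = X.memptr();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (arma::uword)HW * (c + (arma::uword)C * n);
      T* t = dst + (arma::uword)c * N * HW + (arma::uword)n * HW;
      for (int i = 0; i < HW; ++i) t[i] = (T)s[i];
    }
  return X;
}

template <typename T>
static arma::Mat<T> gather_batch(const arma::Mat<T>& X,
                                 const std::vector<int>& ids, int HW) {
  arma::Mat<T> B((arma::uword)ids.size() * HW, X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c)
    for (size_t i = 0; i < ids.size(); ++i)
      std::memcpy(B.memptr() + c * B.n_rows + i * HW,
                  X.memptr() + c * X.n_rows + (arma::uword)ids[i] * HW,
                  sizeof(T) * HW);
  return B;
}

template <typename T>
static void flatten_batch(const arma::Mat<T>& P, int B, int HW4,
                          arma::Mat<T>& F) {
  const int C = P.n_cols;
  F.set_size(B, (arma::uword)HW4 * C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int r = 0; r < HW4; ++r)
        F(b, (arma::uword)c * HW4 + r) = P((arma::uword)b * HW4 + r, c);
}

struct ForwardResult {
  arma::mat probs, logits, features, A; // A = conv2 linear output
  int H2 = 0, W2 = 0;
};

// Inference-mode forward pass (running BN statistics), double precision.
static ForwardResult forward_infer(const CNNWeights& w, const arma::mat& X0,
                                   int H, int W, int B, double eps,
                                   bool keep_A) {
  ForwardResult r;
  arma::mat x = bn_infer(X0, w.bn0, eps);
  x = im2col(x, H, W, B, w.conv1.k) * w.conv1.W;
  x.each_row() += w.conv1.b;
  x = leaky(x);
  x = bn_infer(x, w.bn1, eps);
  arma::umat idx1;
  x = maxpool_fwd(x, H, W, B, idx1);
  const int Hp = H / 2, Wp = W / 2;
  arma::mat A = im2col(x, Hp, Wp, B, w.conv2.k) * w.conv2.W;
  A.each_row() += w.conv2.b;
  if (keep_A) r.A = A;
  r.H2 = Hp; r.W2 = Wp;
  x = leaky(A);
  x = bn_infer(x, w.bn2, eps);
  arma::umat idx2;
  x = maxpool_fwd(x, Hp, Wp, B, idx2);
  const int H4 = Hp / 2, W4 = Wp / 2, HW4 = H4 * W4;
  arma::mat F;
  flatten_batch(x, B, HW4, F);
  arma::mat zd1 = F * w.dense1.W;
  zd1.each_row() += w.dense1.b;
  r.features = leaky(zd1);
  arma::mat h = bn_infer(r.features, w.bn3, eps);
  r.logits = h * w.dense2.W;
  r.logits.each_row() += w.dense2.b;
  arma::mat shifted = r.logits.each_col() - arma::max(r.logits, 1);
  arma::mat e = arma::exp(shifted);
  r.probs = e.each_col() / arma::sum(e, 1);
  return r;
}

// [[Rcpp::export]]
List cpp_cnn_predict(List weights, NumericVector x, int batch_size = 64,
                     bool return_A = false, double bn_eps = 1e-3) {
  CNNWeights w = parse_weights(weights);
  int H, W, C, N;
  arma::mat X = array_to_mat<double>(x, H, W, C, N);
  if (C != w.conv1.cin) stop("input channel count does not match the model");
  const int HW = H * W;
  arma::mat probs(N, w.dense2.W.n_cols), logits(N, w.dense2.W.n_cols);
  arma::mat features(N, w.dense1.W.n_cols);
  int H2 = 0, W2 = 0;
  std::vector<double> Abuf;
  for (int start = 0; start < N; start += batch_size) {
    const int B = std::min(batch_size, N - start);
    std::vector<int> ids(B);
    for (int i = 0; i < B; ++i) ids[i] = start + i;
    arma::mat Xb = gather_batch(X, ids, HW);
    ForwardResult r = forward_infer(w, Xb, H, W, B, bn_eps, return_A);
    probs.rows(start, start + B - 1) = r.probs;
    logits.rows(start, start + B - 1) = r.logits;
    features.rows(start, start + B - 1) = r.features;
    if (return_A) {
      H2 = r.H2; W2 = r.W2;
      const int HW2 = H2 * W2, C2 = r.A.n_cols;
      size_t off = Abuf.size();
      Abuf.resize(off + (size_t)B * HW2 * C2);
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < C2; ++c)
          for (int r2 = 0; r2 < HW2; ++r2)
            Abuf[off + (size_t)b * HW2 * C2 + (size_t)c * HW2 + r2] =
              r.A((arma::uword)b * HW2 + r2, c);
    }
  }
  List out = List::create(
    _["probs"] = wrap(probs), _["logits"] = wrap(logits),
    _["features"] = wrap(features));
  if (return_A) {
    NumericVector A(Abuf.begin(), Abuf.end());
    A.attr("dim") = IntegerVector::create(H2, W2, (int)w.conv2.cout, N);
    out["A"] = A;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_train(List weights, NumericVector x, IntegerVector y, int steps,
                   int batch_size, double lr0, int decay_steps,
                   double decay_rate, int seed, double bn_momentum = 0.99,
                   double bn_eps = 1e-3) {
  typedef float T;
  CNNWeightsT<T> w = convert_weights<T>(parse_weights(weights));
  int H, W, C, N;
  arma::Mat<T> X = array_to_mat<T>(x, H, W, C, N);
  if (C != w.conv1.cin) stop("input channel count does not match the model");
  if ((int)y.size() != N) stop("label count does not match the image batch");
  const int K = w.dense2.W.n_cols;
  for (int i = 0; i < N; ++i)
    if (y[i] < 0 || y[i] >= K) stop("class labels must lie in [0, n_classes)");
  if (batch_size < 2) stop("batch size must be at least 2 (batch normalization)");
  const int HW = H * W;
  const int B = std::min(batch_size, N);
  const T eps = (T)bn_eps, mom = (T)bn_momentum;

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  size_t cursor = (size_t)N; // force initial shuffle

  NumericVector loss_log(steps), lr_log(steps);

  for (int step = 0; step < steps; ++step) {
    const T lr = (T)(lr0 * std::pow(decay_rate, (double)(step / decay_steps)));
    lr_log[step] = (double)lr;
    if (cursor + B > (size_t)N) {
      std::shuffle(perm.begin(), perm.end(), rng);
      cursor = 0;
    }
    std::vector<int> ids(perm.begin() + cursor, perm.begin() + cursor + B);
    cursor += B;

    arma::Mat<T> X0 = gather_batch(X, ids, HW);
    arma::Mat<T> Y(B, K, arma::fill::zeros);
    for (int i = 0; i < B; ++i) Y(i, y[ids[i]]) = (T)1;

    // ---- forward (training mode) ----
    BNCacheT<T> c0, c1, c2, c3;
    arma::Mat<T> a0 = bn_train_fwd(X0, w.bn0, eps, mom, c0);
    arma::Mat<T> cols1 = im2col(a0, H, W, B, w.conv1.k);
    arma::Mat<T> z1 = cols1 * w.conv1.W;
    z1.each_row() += w.conv1.b;
    arma::Mat<T> a1 = leaky(z1);
    arma::Mat<T> b1 = bn_train_fwd(a1, w.bn1, eps, mom, c1);
    arma::umat idx1;
    arma::Mat<T> p1 = maxpool_fwd(b1, H, W, B, idx1);
    const int Hp = H / 2, Wp = W / 2;
    arma::Mat<T> cols2 = im2col(p1, Hp, Wp, B, w.conv2.k);
    arma::Mat<T> z2 = cols2 * w.conv2.W;
    z2.each_row() += w.conv2.b;
    arma::Mat<T> a2 = leaky(z2);
    arma::Mat<T> b2 = bn_train_fwd(a2, w.bn2, eps, mom, c2);
    arma::umat idx2;
    arma::Mat<T> p2 = maxpool_fwd(b2, Hp, Wp, B, idx2);
    const int H4 = Hp / 2, W4 = Wp / 2, HW4 = H4 * W4;
    const int C2 = p2.n_cols;
    arma::Mat<T> F;
    flatten_batch(p2, B, HW4, F);
    arma::Mat<T> zd1 = F * w.dense1.W;
    zd1.each_row() += w.dense1.b;
    arma::Mat<T> ad1 = leaky(zd1);
    arma::Mat<T> h3 = bn_train_fwd(ad1, w.bn3, eps, mom, c3);
    arma::Mat<T> logits = h3 * w.dense2.W;
    logits.each_row() += w.dense2.b;
    arma::Mat<T> shifted = logits.each_col() - arma::max(logits, 1);
    arma::Mat<T> e = arma::exp(shifted);
    arma::Mat<T> P = e.each_col() / arma::sum(e, 1);

    double loss = 0.0;
    for (int i = 0; i < B; ++i)
      loss -= std::log(std::max((double)P(i, y[ids[i]]), 1e-12));
    loss /= B;
    loss_log[step] = loss;
    if (!std::isfinite(loss))
      stop("training diverged: non-finite loss at step %d", step + 1);

    // ---- backward ----
    arma::Mat<T> dlogits = (P - Y) / (T)B;
    arma::Mat<T> dWd2 = h3.t() * dlogits;
    arma::Row<T> dbd2 = arma::sum(dlogits, 0);
    arma::Mat<T> dh3 = dlogits * w.dense2.W.t();
    arma::Row<T> dg3, db3;
    arma::Mat<T> dad1 = bn_train_bwd(dh3, c3, w.bn3, dg3, db3);
    leaky_grad_inplace(dad1, zd1); // dad1 is now dzd1
    arma::Mat<T>& dzd1 = dad1;
    arma::Mat<T> dF = dzd1 * w.dense1.W.t();
    // fused weight gradient + update: W -= lr * F^T * dzd1
    w.dense1.W += (F.t() * (-lr * dzd1));
    w.dense1.b -= lr * arma::sum(dzd1, 0);
    arma::Mat<T> dp2((arma::uword)B * HW4, C2);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C2; ++c)
        for (int r2 = 0; r2 < HW4; ++r2)
          dp2((arma::uword)b * HW4 + r2, c) = dF(b, (arma::uword)c * HW4 + r2);
    arma::Mat<T> db2m = maxpool_bwd(dp2, idx2, b2.n_rows);
    arma::Row<T> dg2, dbt2;
    arma::Mat<T> da2 = bn_train_bwd(db2m, c2, w.bn2, dg2, dbt2);
    leaky_grad_inplace(da2, z2);
    arma::Mat<T>& dz2 = da2;
    arma::Mat<T> dW2 = cols2.t() * dz2;
    arma::Row<T> db2 = arma::sum(dz2, 0);
    arma::Mat<T> dcols2 = dz2 * w.conv2.W.t();
    arma::Mat<T> dp1 = col2im(dcols2, Hp, Wp, B, w.conv2.k, w.conv2.cin);
    arma::Mat<T> db1m = maxpool_bwd(dp1, idx1, b1.n_rows);
    arma::Row<T> dg1, dbt1;
    arma::Mat<T> da1 = bn_train_bwd(db1m, c1, w.bn1, dg1, dbt1);
    leaky_grad_inplace(da1, z1);
    arma::Mat<T>& dz1 = da1;
    arma::Mat<T> dW1 = cols1.t() * dz1;
    arma::Row<T> db1 = arma::sum(dz1, 0);
    arma::Mat<T> dcols1 = dz1 * w.conv1.W.t();
    arma::Mat<T> da0 = col2im(dcols1, H, W, B, w.conv1.k, w.conv1.cin);
    arma::Row<T> dg0, dbt0;
    bn_train_bwd(da0, c0, w.bn0, dg0, dbt0); // input gradient unused

    // ---- SGD update (dense1 already updated above) ----
    w.dense2.W -= lr * dWd2;  w.dense2.b -= lr * dbd2;
    w.bn3.gamma -= lr * dg3.t();  w.bn3.beta -= lr * db3.t();
    w.bn2.gamma -= lr * dg2.t();  w.bn2.beta -= lr * dbt2.t();
    w.conv2.W -= lr * dW2;  w.conv2.b -= lr * db2;
    w.bn1.gamma -= lr * dg1.t();  w.bn1.beta -= lr * dbt1.t();
    w.conv1.W -= lr * dW1;  w.conv1.b -= lr * db1;
    w.bn0.gamma -= lr * dg0.t();  w.bn0.beta -= lr * dbt0.t();

    if (step % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["weights"] = weights_to_list(w, weights.attr("input_shape")),
    _["loss"] = loss_log,
    _["lr"] = lr_log);
}

// Single-image stride-1 same-padded cross-correlation, used by the
// R-level conv2d() operation. Double precision.
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector img, NumericVector kern,
                         NumericVector bias) {
  IntegerVector di = img.attr("dim"), dk = kern.attr("dim");
  if (di.size() != 3) stop("image must be a (H, W, C) array");
  if (dk.size() != 4 || dk[0] != dk[1])
    stop("kernels must be a (k, k, cin, cout) array");
  const int H = di[0], W = di[1], Cin = di[2];
  const int k = dk[0], cout = dk[3];
  if (dk[2] != Cin) stop("kernel input channels do not match the image");
  if (k % 2 == 0) stop("only odd kernel sizes are supported (same padding)");
  if ((int)bias.size() != cout) stop("bias length must equal the kernel count");
  const int HW = H * W;
  arma::mat X(img.begin(), HW, Cin); // (h, w) column-major rows
  arma::mat Wm(kern.begin(), (arma::uword)k * k * Cin, cout);
  arma::mat out = im2col(X, H, W, 1, k) * Wm;
  for (int c = 0; c < cout; ++c) out.col(c) += bias[c];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(H, W, cout);
  return res;
}
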