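// Encoder-decoder forecaster internals.
//
// Encoder: two stacked LSTM layers (64, 16 units) consuming the normalized
// 8 x P past block, followed by a linear map to the 32-d latent vector.
// Decoder: the latent concatenated with the H future stimulation bits,
// through 5 rectified-linear layers of 32 units and a linear head of H
// units. Training is mean-squared-error with gradients derived by
// backpropagation through time below; the Adam update lives on the R side.
//
// The kernels are templated on the element type; the exported entry
// points use double precision (the faster path under this BLAS), and the
// same instantiation backs the finite-difference gradient checks in the
// test suite.
//
// The input-to-gate contributions W * x_t are independent of the
// recurrence, so they are computed for all timesteps in one large GEMM
// (and likewise for the weight gradients in the backward pass); only the
// U * h recurrences run step by step.
//
// Weight list layout (fixed names, see R/forecast.R):
//   W1 (256x8)  U1 (256x64)  b1 (256)   -- LSTM layer 1, gate order i,f,g,o
//   W2 (64x64)  U2 (64x16)   b2 (64)    -- LSTM layer 2
//   Wz (32x16)  bz (32)                 -- latent projection
//   D1 (32x(32+H)) .. D5 (32x32), bd1..bd5 (32)
//   Wo (Hx32)   bo (H)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

template <typename T> struct Wts {
  Mat<T> W1, U1, W2, U2, Wz, D[6], Wo;
  Col<T> b1, b2, bz, bd[6], bo;
};

template <typename T>
static Wts<T> unpack(const Rcpp::List& w) {
  Wts<T> o;
  auto getM = [&](const char* nm) {
    return conv_to<Mat<T>>::from(Rcpp::as<mat>(w[nm]));
  };
  auto getV = [&](const char* nm) {
    return conv_to<Col<T>>::from(Rcpp::as<vec>(w[nm]));
  };
  o.W1 = getM("W1"); o.U1 = getM("U1"); o.b1 = getV("b1");
  o.W2 = getM("W2"); o.U2 = getM("U2"); o.b2 = getV("b2");
  o.Wz = getM("Wz"); o.bz = getV("bz");
  for (int k = 1; k <= 5; ++k) {
    o.D[k] = getM(("D" + std::to_string(k)).c_str());
    o.bd[k] = getV(("bd" + std::to_string(k)).c_str());
  }
  o.Wo = getM("Wo"); o.bo = getV("bo");
  return o;
}

template <typename T> struct LSTMCache {
  Mat<T> h;      // n x B*(P+1), column-block t holds h_t (block 0 = zeros)
  Mat<T> c;      // n x B*(P+1)
  Mat<T> gates;  // 4n x B*P, post-activation [i; f; g; o]
  uword B, P;
};

template <typename T>
static inline Mat<T> sigm(const Mat<T>& x) {
  return T(1) / (T(1) + exp(-x));
}

// Xin: d x B*P with column-block t = x_t (B columns per block).
template <typename T>
static LSTMCache<T> lstm_forward(const Mat<T>& W, const Mat<T>& U,
                                 const Col<T>& b, const Mat<T>& Xin,
                                 uword B, uword P) {
  const uword n = U.n_cols;
  LSTMCache<T> cc;
  cc.B = B; cc.P = P;
  cc.h.zeros(n, B * (P + 1));
  cc.c.zeros(n, B * (P + 1));
  cc.gates.set_size(4 * n, B * P);
  Mat<T> Wx = W * Xin;              // one large GEMM for all timesteps
  Wx.each_col() += b;
  for (uword t = 0; t < P; ++t) {
    const uword c0 = t * B, c1 = t * B + B - 1;
    Mat<T> a = Wx.cols(c0, c1) + U * cc.h.cols(c0, c1);
    Mat<T> i = sigm<T>(a.rows(0, n - 1));
    Mat<T> f = sigm<T>(a.rows(n, 2 * n - 1));
    Mat<T> g = tanh(a.rows(2 * n, 3 * n - 1));
    Mat<T> o = sigm<T>(a.rows(3 * n, 4 * n - 1));
    Mat<T> cnew = f % cc.c.cols(c0, c1) + i % g;
    cc.c.cols(c0 + B, c1 + B) = cnew;
    cc.h.cols(c0 + B, c1 + B) = o % tanh(cnew);
    cc.gates.submat(0, c0, n - 1, c1) = i;
    cc.gates.submat(n, c0, 2 * n - 1, c1) = f;
    cc.gates.submat(2 * n, c0, 3 * n - 1, c1) = g;
    cc.gates.submat(3 * n, c0, 4 * n - 1, c1) = o;
  }
  return cc;
}

// dH_ext: n x B*P gradients flowing into h_t from outside the layer.
template <typename T>
static void lstm_backward(const Mat<T>& W, const Mat<T>& U,
                          const Mat<T>& Xin, const LSTMCache<T>& cc,
                          const Mat<T>& dH_ext, Mat<T>& dW, Mat<T>& dU,
                          Col<T>& db, Mat<T>& dX) {
  const uword n = U.n_cols, B = cc.B, P = cc.P;
  Mat<T> DA(4 * n, B * P);          // pre-activation gate gradients
  Mat<T> dh_rec(n, B, fill::zeros), dc(n, B, fill::zeros);
  for (uword t = P; t-- > 0;) {
    const uword c0 = t * B, c1 = t * B + B - 1;
    const Mat<T> i = cc.gates.submat(0, c0, n - 1, c1);
    const Mat<T> f = cc.gates.submat(n, c0, 2 * n - 1, c1);
    const Mat<T> g = cc.gates.submat(2 * n, c0, 3 * n - 1, c1);
    const Mat<T> o = cc.gates.submat(3 * n, c0, 4 * n - 1, c1);
    const Mat<T> tc = tanh(cc.c.cols(c0 + B, c1 + B));
    Mat<T> dh = dH_ext.cols(c0, c1) + dh_rec;
    Mat<T> do_ = dh % tc;
    dc += dh % o % (T(1) - square(tc));
    DA.submat(0, c0, n - 1, c1) = (dc % g) % i % (T(1) - i);
    DA.submat(n, c0, 2 * n - 1, c1) =
        (dc % cc.c.cols(c0, c1)) % f % (T(1) - f);
    DA.submat(2 * n, c0, 3 * n - 1, c1) = (dc % i) % (T(1) - square(g));
    DA.submat(3 * n, c0, 4 * n - 1, c1) = do_ % o % (T(1) - o);
    const Mat<T> da = DA.cols(c0, c1);
    dh_rec = U.t() * da;
    dc = dc % f;
  }
  dW = DA * Xin.t();                // one large GEMM each
  dU = DA * cc.h.cols(0, B * P - 1).t();
  db = sum(DA, 1);
  dX = W.t() * DA;
}

// Reshape an R array (8 x P x B, slice = sample) into d x B*P with
// column-block t = x_t across the batch.
template <typename T>
static Mat<T> to_time_major(const cube& X) {
  const uword d = X.n_rows, P = X.n_cols, B = X.n_slices;
  Mat<T> out(d, B * P);
  for (uword t = 0; t < P; ++t)
    out.cols(t * B, t * B + B - 1) =
        conv_to<Mat<T>>::from(X.col_as_mat(t));
  return out;
}

template <typename T>
static Mat<T> encoder_forward(const Wts<T>& w, const Mat<T>& Xin, uword B,
                              uword P, LSTMCache<T>& c1, LSTMCache<T>& c2) {
  c1 = lstm_forward<T>(w.W1, w.U1, w.b1, Xin, B, P);
  c2 = lstm_forward<T>(w.W2, w.U2, w.b2, c1.h.cols(B, B * P + B - 1), B, P);
  Mat<T> z = w.Wz * c2.h.cols(B * P, B * P + B - 1);
  z.each_col() += w.bz;
  return z;
}

// Decoder forward; acts stores the 5 hidden activations plus the input.
template <typename T>
static Mat<T> decoder_forward(const Wts<T>& w, const Mat<T>& Z,
                              const Mat<T>& S, std::vector<Mat<T>>& acts) {
  acts.clear();
  Mat<T> a = join_cols(Z, S);
  acts.push_back(a);
  for (int k = 1; k <= 5; ++k) {
    a = w.D[k] * a;
    a.each_col() += w.bd[k];
    a = clamp(a, T(0), std::numeric_limits<T>::max());  // relu
    acts.push_back(a);
  }
  Mat<T> y = w.Wo * a;
  y.each_col() += w.bo;
  return y;
}

template <typename T>
static mat encode_impl(const Rcpp::List& weights, const cube& X) {
  Wts<T> w = unpack<T>(weights);
  LSTMCache<T> c1, c2;
  Mat<T> Xin = to_time_major<T>(X);
  return conv_to<mat>::from(
      encoder_forward<T>(w, Xin, X.n_slices, X.n_cols, c1, c2));
}

template <typename T>
static mat decode_impl(const Rcpp::List& weights, const mat& Z,
                       const mat& S) {
  Wts<T> w = unpack<T>(weights);
  std::vector<Mat<T>> acts;
  return conv_to<mat>::from(decoder_forward<T>(
      w, conv_to<Mat<T>>::from(Z), conv_to<Mat<T>>::from(S), acts));
}

template <typename T>
static mat forward_impl(const Rcpp::List& weights, const cube& X,
                        const mat& S) {
  Wts<T> w = unpack<T>(weights);
  LSTMCache<T> c1, c2;
  Mat<T> Xin = to_time_major<T>(X);
  Mat<T> z = encoder_forward<T>(w, Xin, X.n_slices, X.n_cols, c1, c2);
  std::vector<Mat<T>> acts;
  return conv_to<mat>::from(
      decoder_forward<T>(w, z, conv_to<Mat<T>>::from(S), acts));
}

// Full forward + backward pass for one batch. X: 8 x P x B (R array),
// S: H x B future stimulations, Y: H x B ground truth.
template <typename T>
static Rcpp::List grad_impl(const Rcpp::List& weights, const cube& X,
                            const mat& Sd, const mat& Yd) {
  const uword P = X.n_cols, B = X.n_slices, H = Yd.n_rows;
  Wts<T> w = unpack<T>(weights);
  Mat<T> S = conv_to<Mat<T>>::from(Sd);
  Mat<T> Y = conv_to<Mat<T>>::from(Yd);
  Mat<T> Xin = to_time_major<T>(X);
  LSTMCache<T> c1, c2;
  Mat<T> z = encoder_forward<T>(w, Xin, B, P, c1, c2);
  std::vector<Mat<T>> acts;
  Mat<T> yhat = decoder_forward<T>(w, z, S, acts);

  const double loss = accu(square(yhat - Y)) / double(H * B);
  Mat<T> dy = T(2) * (yhat - Y) / T(H * B);

  // decoder backward
  Mat<T> dWo = dy * acts[5].t();
  Col<T> dbo = sum(dy, 1);
  Mat<T> da = w.Wo.t() * dy;
  Mat<T> dD[6];
  Col<T> dbd[6];
  for (int k = 5; k >= 1; --k) {
    da %= conv_to<Mat<T>>::from(acts[k] > T(0));  // relu'
    dD[k] = da * acts[k - 1].t();
    dbd[k] = sum(da, 1);
    da = w.D[k].t() * da;
  }
  Mat<T> dz = da.rows(0, 31);  // gradients w.r.t. S are discarded

  // latent projection backward
  Mat<T> dWz = dz * c2.h.cols(B * P, B * P + B - 1).t();
  Col<T> dbz = sum(dz, 1);

  // encoder backward (layer 2 receives external gradient only at t = P)
  const uword n2 = c2.h.n_rows;
  Mat<T> dH2(n2, B * P, fill::zeros);
  dH2.cols(B * (P - 1), B * P - 1) = w.Wz.t() * dz;
  Mat<T> dW2, dU2, dX2;
  Col<T> db2;
  lstm_backward<T>(w.W2, w.U2, c1.h.cols(B, B * P + B - 1), c2, dH2,
                   dW2, dU2, db2, dX2);

  Mat<T> dW1, dU1, dX1;
  Col<T> db1;
  lstm_backward<T>(w.W1, w.U1, Xin, c1, dX2, dW1, dU1, db1, dX1);

  auto out = [](const Mat<T>& m) { return conv_to<mat>::from(m); };
  auto outv = [](const Col<T>& v) { return conv_to<vec>::from(v); };
  Rcpp::List g = Rcpp::List::create(
      Rcpp::Named("W1") = out(dW1), Rcpp::Named("U1") = out(dU1),
      Rcpp::Named("b1") = outv(db1), Rcpp::Named("W2") = out(dW2),
      Rcpp::Named("U2") = out(dU2), Rcpp::Named("b2") = outv(db2),
      Rcpp::Named("Wz") = out(dWz), Rcpp::Named("bz") = outv(dbz));
  for (int k = 1; k <= 5; ++k) {
    g["D" + std::to_string(k)] = out(dD[k]);
    g["bd" + std::to_string(k)] = outv(dbd[k]);
  }
  g["Wo"] = out(dWo);
  g["bo"] = outv(dbo);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = g);
}

// [[Rcpp::export(name = ".fc_encode")]]
arma::mat fc_encode(const Rcpp::List& weights, const arma::cube& X) {
  return encode_impl<double>(weights, X);
}

// [[Rcpp::export(name = ".fc_decode")]]
arma::mat fc_decode(const Rcpp::List& weights, const arma::mat& Z,
                    const arma::mat& S) {
  return decode_impl<double>(weights, Z, S);
}

// [[Rcpp::export(name = ".fc_forward")]]
arma::mat fc_forward(const Rcpp::List& weights, const arma::cube& X,
                     const arma::mat& S) {
  return forward_impl<double>(weights, X, S);
}

// [[Rcpp::export(name = ".fc_grad")]]
Rcpp::List fc_grad(const Rcpp::List& weights, const arma::cube& X,
                   const arma::mat& S, const arma::mat& Y) {
  return grad_impl<double>(weights, X, S, Y);
}

// single-precision instantiation, kept as a cross-precision consistency
// reference for the tests
// [[Rcpp::export(name = ".fc_grad_sgl")]]
Rcpp::List fc_grad_sgl(const Rcpp::List& weights, const arma::cube& X,
                       const arma::mat& S, const arma::mat& Y) {
  return grad_impl<float>(weights, X, S, Y);
}
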