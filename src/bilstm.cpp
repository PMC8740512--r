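// Bidirectional LSTM + per-frame MLP sequence regressor.
//
// Architecture: input dropout -> BiLSTM (forward + time-reversed passes,
// outputs averaged elementwise, full sequence retained) -> dropout ->
// per-frame MLP with rectifier hidden layers -> linear scalar per frame.
// Trained with Adam on per-frame MSE. No framework dependency: forward,
// BPTT, and the optimizer are implemented here and validated by
// finite-difference gradient checks in the test suite.
//
// Batches are stored frame-major: a batch of N sequences of length T is a
// (N*T) x K matrix whose row block [t*N, t*N+N) holds frame t of every
// sequence. The input projection and all MLP work then run as single
// GEMMs; only the recurrent update walks the sequence.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Wx_f, Wh_f, Wx_b, Wh_b;   // LSTM kernels, (4U x F) and (4U x U)
  vec b_f, b_b;                  // LSTM biases (4U)
  std::vector<mat> W;            // MLP weights, last layer is the linear head
  std::vector<vec> b;
};

struct LSTMCache {
  mat I, F, G, O, C, H;          // (N*T) x U, frame-major
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

Params unpack(const Rcpp::List& w) {
  Params p;
  p.Wx_f = Rcpp::as<mat>(w["Wx_f"]); p.Wh_f = Rcpp::as<mat>(w["Wh_f"]);
  p.b_f = Rcpp::as<vec>(w["b_f"]);
  p.Wx_b = Rcpp::as<mat>(w["Wx_b"]); p.Wh_b = Rcpp::as<mat>(w["Wh_b"]);
  p.b_b = Rcpp::as<vec>(w["b_b"]);
  Rcpp::List mw = w["mlp_W"], mb = w["mlp_b"];
  for (int i = 0; i < mw.size(); ++i) {
    p.W.push_back(Rcpp::as<mat>(mw[i]));
    p.b.push_back(Rcpp::as<vec>(mb[i]));
  }
  return p;
}

Rcpp::List pack(const Params& p) {
  Rcpp::List mw(p.W.size()), mb(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) { mw[i] = p.W[i]; mb[i] = p.b[i]; }
  return Rcpp::List::create(
      Rcpp::Named("Wx_f") = p.Wx_f, Rcpp::Named("Wh_f") = p.Wh_f,
      Rcpp::Named("b_f") = p.b_f, Rcpp::Named("Wx_b") = p.Wx_b,
      Rcpp::Named("Wh_b") = p.Wh_b, Rcpp::Named("b_b") = p.b_b,
      Rcpp::Named("mlp_W") = mw, Rcpp::Named("mlp_b") = mb);
}

// one directional pass over the frame-major batch
void lstm_forward(const mat& X, uword N, uword T, const mat& Wx,
                  const mat& Wh, const vec& b, bool reverse, LSTMCache& ca) {
  const uword U = Wh.n_cols;
  mat ZX = X * Wx.t();             // input projection, one GEMM
  ZX.each_row() += b.t();
  ca.I.set_size(N * T, U); ca.F.set_size(N * T, U); ca.G.set_size(N * T, U);
  ca.O.set_size(N * T, U); ca.C.set_size(N * T, U); ca.H.set_size(N * T, U);
  mat h_prev(N, U, fill::zeros), c_prev(N, U, fill::zeros);
  mat Z(N, 4 * U);
  for (uword s = 0; s < T; ++s) {
    const uword t = reverse ? T - 1 - s : s;
    const uword r0 = t * N, r1 = t * N + N - 1;
    Z = ZX.rows(r0, r1) + h_prev * Wh.t();
    ca.I.rows(r0, r1) = sigm(Z.cols(0, U - 1));
    ca.F.rows(r0, r1) = sigm(Z.cols(U, 2 * U - 1));
    ca.G.rows(r0, r1) = tanh(Z.cols(2 * U, 3 * U - 1));
    ca.O.rows(r0, r1) = sigm(Z.cols(3 * U, 4 * U - 1));
    c_prev = ca.F.rows(r0, r1) % c_prev + ca.I.rows(r0, r1) % ca.G.rows(r0, r1);
    ca.C.rows(r0, r1) = c_prev;
    h_prev = ca.O.rows(r0, r1) % tanh(c_prev);
    ca.H.rows(r0, r1) = h_prev;
  }
}

// BPTT for one direction; dH is the gradient w.r.t. this direction's output
void lstm_backward(const mat& X, uword N, uword T, const mat& Wh,
                   const LSTMCache& ca, const mat& dH, bool reverse,
                   mat& dWx, mat& dWh, vec& db) {
  const uword U = Wh.n_cols;
  dWh.zeros(4 * U, U);
  mat dZall(N * T, 4 * U);
  mat dh_next(N, U, fill::zeros), dc_next(N, U, fill::zeros);
  const mat zerosNU(N, U, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const uword t = reverse ? T - 1 - s : s;
    const uword r0 = t * N, r1 = t * N + N - 1;
    // previous processing step's state lives at the neighbouring time block
    const uword q0 = (reverse ? t + 1 : t - 1) * N;
    const mat tc = tanh(ca.C.rows(r0, r1));
    const mat dh = dH.rows(r0, r1) + dh_next;
    const mat dc = dc_next + dh % ca.O.rows(r0, r1) % (1.0 - tc % tc);
    dZall.submat(r0, 0, r1, U - 1) =
        dc % ca.G.rows(r0, r1) % ca.I.rows(r0, r1) % (1.0 - ca.I.rows(r0, r1));
    dZall.submat(r0, U, r1, 2 * U - 1) =
        dc % (s > 0 ? mat(ca.C.rows(q0, q0 + N - 1)) : zerosNU) %
        ca.F.rows(r0, r1) % (1.0 - ca.F.rows(r0, r1));
    dZall.submat(r0, 2 * U, r1, 3 * U - 1) =
        dc % ca.I.rows(r0, r1) % (1.0 - ca.G.rows(r0, r1) % ca.G.rows(r0, r1));
    dZall.submat(r0, 3 * U, r1, 4 * U - 1) =
        dh % tc % ca.O.rows(r0, r1) % (1.0 - ca.O.rows(r0, r1));
    const mat dZt = dZall.rows(r0, r1);
    if (s > 0) dWh += dZt.t() * ca.H.rows(q0, q0 + N - 1);
    dh_next = dZt * Wh;
    dc_next = dc % ca.F.rows(r0, r1);
  }
  dWx = dZall.t() * X;             // one GEMM for the input-kernel gradient
  db = sum(dZall, 0).t();
}

struct ForwardCache {
  LSTMCache fwd, bwd;
  mat Hm;                          // merged LSTM output, post-dropout
  std::vector<mat> A;              // MLP activations; A[0] = Hm
  std::vector<mat> Z;              // MLP pre-activations
  vec yhat;                        // N*T predictions
};

// full forward pass; X must already have input dropout applied
double forward_pass(const Params& p, const mat& X, uword N, uword T,
                    const vec& y, const mat* drop_mask, double keep,
                    ForwardCache& fc, bool want_loss) {
  lstm_forward(X, N, T, p.Wx_f, p.Wh_f, p.b_f, false, fc.fwd);
  lstm_forward(X, N, T, p.Wx_b, p.Wh_b, p.b_b, true, fc.bwd);
  fc.Hm = 0.5 * (fc.fwd.H + fc.bwd.H);
  if (drop_mask) fc.Hm = fc.Hm % (*drop_mask) / keep;
  const size_t L = p.W.size();
  fc.A.assign(L + 1, mat()); fc.Z.assign(L, mat());
  fc.A[0] = fc.Hm;
  for (size_t l = 0; l < L; ++l) {
    fc.Z[l] = fc.A[l] * p.W[l].t();
    fc.Z[l].each_row() += p.b[l].t();
    if (l + 1 < L) {
      fc.A[l + 1] = fc.Z[l];
      fc.A[l + 1].for_each([](double& v) { if (v < 0.0) v = 0.0; });
    } else {
      fc.A[l + 1] = fc.Z[l];
    }
  }
  fc.yhat = fc.A[L].col(0);
  if (!want_loss) return 0.0;
  const vec d = fc.yhat - y;
  return dot(d, d) / double(N * T);
}

// gradients of the mean-squared-error loss w.r.t. every parameter
void backward_pass(const Params& p, const mat& X, uword N, uword T,
                   const vec& y, const mat* drop_mask, double keep,
                   const ForwardCache& fc, Params& g) {
  const size_t L = p.W.size();
  g.W.assign(L, mat()); g.b.assign(L, vec());
  mat dA = mat(2.0 * (fc.yhat - y) / double(N * T));
  for (size_t l = L; l-- > 0;) {
    mat dZ = dA;
    if (l + 1 < L) dZ %= conv_to<mat>::from(fc.Z[l] > 0.0);
    g.W[l] = dZ.t() * fc.A[l];
    g.b[l] = sum(dZ, 0).t();
    dA = dZ * p.W[l];
  }
  if (drop_mask) dA = dA % (*drop_mask) / keep;
  const mat dHdir = 0.5 * dA;
  lstm_backward(X, N, T, p.Wh_f, fc.fwd, dHdir, false, g.Wx_f, g.Wh_f, g.b_f);
  lstm_backward(X, N, T, p.Wh_b, fc.bwd, dHdir, true, g.Wx_b, g.Wh_b, g.b_b);
}

// frame-major batch (N*T) x F from a list of T x F matrices
mat stack_batch(const Rcpp::List& X, const std::vector<int>& idx) {
  const mat first = Rcpp::as<mat>(X[idx[0]]);
  const uword T = first.n_rows, F = first.n_cols, N = idx.size();
  mat out(N * T, F);
  for (uword n = 0; n < N; ++n) {
    const mat xi = (n == 0) ? first : Rcpp::as<mat>(X[idx[n]]);
    if (xi.n_rows != T || xi.n_cols != F)
      Rcpp::stop("all training sequences must share length and width");
    for (uword t = 0; t < T; ++t) out.row(t * N + n) = xi.row(t);
  }
  return out;
}

vec stack_targets(const Rcpp::List& y, const std::vector<int>& idx, uword T) {
  const uword N = idx.size();
  vec out(N * T);
  for (uword n = 0; n < N; ++n) {
    const vec yi = Rcpp::as<vec>(y[idx[n]]);
    if (yi.n_elem != T)
      Rcpp::stop("target length does not match sequence length");
    for (uword t = 0; t < T; ++t) out(t * N + n) = yi(t);
  }
  return out;
}

mat glorot(uword rows, uword cols, uword fan_in, uword fan_out,
           std::mt19937_64& rng) {
  const double lim = std::sqrt(6.0 / double(fan_in + fan_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat out(rows, cols);
  for (uword j = 0; j < cols; ++j)
    for (uword i = 0; i < rows; ++i) out(i, j) = u(rng);
  return out;
}

mat dropout_mask(uword rows, uword cols, double rate, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> u(0.0, 1.0);
  mat m(rows, cols);
  for (uword j = 0; j < cols; ++j)
    for (uword i = 0; i < rows; ++i) m(i, j) = u(rng) >= rate ? 1.0 : 0.0;
  return m;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List nn_init_weights(int n_features, int units,
                           Rcpp::IntegerVector mlp_sizes, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  const uword F = n_features, U = units;
  Params p;
  p.Wx_f = glorot(4 * U, F, F, 4 * U, rng);
  p.Wh_f = glorot(4 * U, U, U, 4 * U, rng);
  p.Wx_b = glorot(4 * U, F, F, 4 * U, rng);
  p.Wh_b = glorot(4 * U, U, U, 4 * U, rng);
  p.b_f.zeros(4 * U); p.b_b.zeros(4 * U);
  p.b_f.subvec(U, 2 * U - 1).ones();   // forget-gate bias 1
  p.b_b.subvec(U, 2 * U - 1).ones();
  uword prev = U;
  for (int l = 0; l < mlp_sizes.size(); ++l) {
    const uword h = mlp_sizes[l];
    p.W.push_back(glorot(h, prev, prev, h, rng));
    p.b.push_back(vec(h, fill::zeros));
    prev = h;
  }
  p.W.push_back(glorot(1, prev, prev, 1, rng));
  p.b.push_back(vec(1, fill::zeros));
  return pack(p);
}

// [[Rcpp::export]]
Rcpp::List nn_predict_cpp(Rcpp::List weights, Rcpp::List X) {
  const Params p = unpack(weights);
  Rcpp::List out(X.size());
  for (int i = 0; i < X.size(); ++i) {
    const std::vector<int> idx = {i};
    const mat Xb = stack_batch(X, idx);
    ForwardCache fc;
    vec dummy;
    forward_pass(p, Xb, 1, Xb.n_rows, dummy, nullptr, 1.0, fc, false);
    out[i] = Rcpp::NumericVector(fc.yhat.begin(), fc.yhat.end());
  }
  return out;
}

// loss and gradients with dropout disabled; used by the finite-difference
// gradient check in the test suite
// [[Rcpp::export]]
Rcpp::List nn_loss_grad(Rcpp::List weights, Rcpp::List X, Rcpp::List y) {
  const Params p = unpack(weights);
  std::vector<int> idx(X.size());
  for (int i = 0; i < X.size(); ++i) idx[i] = i;
  const mat Xb = stack_batch(X, idx);
  const uword N = idx.size(), T = Xb.n_rows / N;
  const vec yb = stack_targets(y, idx, T);
  ForwardCache fc;
  const double loss = forward_pass(p, Xb, N, T, yb, nullptr, 1.0, fc, true);
  Params g;
  backward_pass(p, Xb, N, T, yb, nullptr, 1.0, fc, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(g));
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(Rcpp::List weights, Rcpp::List X, Rcpp::List y,
                        Rcpp::List cfg, int seed) {
  Params p = unpack(weights);
  const double lr = cfg["learning_rate"];
  const int batch_size = cfg["batch_size"];
  const int max_epochs = cfg["max_epochs"];
  const double min_delta = cfg["min_delta"];
  const int patience = cfg["patience"];
  const double p_in = cfg["input_dropout"];
  const double p_mid = cfg["post_lstm_dropout"];
  const int n = X.size();
  if (n == 0) Rcpp::stop("empty training set");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);

  // flat views over parameters for the optimizer, pack() order
  std::vector<mat*> pw = {&p.Wx_f, &p.Wh_f, &p.Wx_b, &p.Wh_b};
  std::vector<vec*> pv = {&p.b_f, &p.b_b};
  for (auto& W : p.W) pw.push_back(&W);
  for (auto& b : p.b) pv.push_back(&b);
  std::vector<mat> mW(pw.size()), vW(pw.size());
  std::vector<vec> mB(pv.size()), vB(pv.size());
  for (size_t i = 0; i < pw.size(); ++i) {
    mW[i].zeros(pw[i]->n_rows, pw[i]->n_cols);
    vW[i].zeros(pw[i]->n_rows, pw[i]->n_cols);
  }
  for (size_t i = 0; i < pv.size(); ++i) {
    mB[i].zeros(pv[i]->n_elem); vB[i].zeros(pv[i]->n_elem);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  long step = 0;

  std::vector<double> history;
  double best = datum::inf;
  int wait = 0, stopped_epoch = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    long frames = 0;
    for (int start = 0; start < n; start += batch_size) {
      const std::vector<int> idx(order.begin() + start,
                                 order.begin() + std::min(n, start + batch_size));
      mat Xb = stack_batch(X, idx);
      const uword N = idx.size(), T = Xb.n_rows / N, U = p.Wh_f.n_cols;
      const vec yb = stack_targets(y, idx, T);
      if (p_in > 0)
        Xb %= dropout_mask(Xb.n_rows, Xb.n_cols, p_in, rng) / (1.0 - p_in);
      mat m_mid;
      const mat* mid_ptr = nullptr;
      if (p_mid > 0) {
        m_mid = dropout_mask(N * T, U, p_mid, rng);
        mid_ptr = &m_mid;
      }
      ForwardCache fc;
      const double loss =
          forward_pass(p, Xb, N, T, yb, mid_ptr, 1.0 - p_mid, fc, true);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", epoch + 1);
      epoch_loss += loss * double(N * T);
      frames += N * T;
      Params g;
      backward_pass(p, Xb, N, T, yb, mid_ptr, 1.0 - p_mid, fc, g);
      std::vector<mat*> gw = {&g.Wx_f, &g.Wh_f, &g.Wx_b, &g.Wh_b};
      std::vector<vec*> gv = {&g.b_f, &g.b_b};
      for (auto& W : g.W) gw.push_back(&W);
      for (auto& b : g.b) gv.push_back(&b);
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, step);
      const double bc2 = 1.0 - std::pow(beta2, step);
      for (size_t i = 0; i < pw.size(); ++i) {
        mW[i] = beta1 * mW[i] + (1 - beta1) * (*gw[i]);
        vW[i] = beta2 * vW[i] + (1 - beta2) * square(*gw[i]);
        *pw[i] -= lr * (mW[i] / bc1) / (sqrt(vW[i] / bc2) + eps);
      }
      for (size_t i = 0; i < pv.size(); ++i) {
        mB[i] = beta1 * mB[i] + (1 - beta1) * (*gv[i]);
        vB[i] = beta2 * vB[i] + (1 - beta2) * square(*gv[i]);
        *pv[i] -= lr * (mB[i] / bc1) / (sqrt(vB[i] / bc2) + eps);
      }
    }
    epoch_loss /= double(frames);
    history.push_back(epoch_loss);
    stopped_epoch = epoch + 1;
    if (best - epoch_loss > min_delta) {
      best = epoch_loss;
      wait = 0;
    } else {
      if (++wait >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = pack(p),
      Rcpp::Named("history") = history,
      Rcpp::Named("epochs") = stopped_epoch,
      Rcpp::Named("early_stopped") = stopped_epoch < max_epochs);
}
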