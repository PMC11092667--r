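// Compact single-layer LSTM one-step-ahead predictor.
//
// Architecture: input layer (C channels) -> LSTM hidden layer (H units) ->
// dropout (training only) -> linear readout back to C channels.  Trained
// full-batch (all trials at once) with Adam on the mean squared one-step
// prediction error plus an L2 penalty on the input kernel Wx.
//
// Gate layout inside the 4H-wide kernels: [input | forget | candidate | output].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LSTMParams {
  mat Wx, Wh, Wy;
  rowvec b, by;
};

static LSTMParams init_params(int C, int H, std::mt19937_64& rng) {
  LSTMParams p;
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  double gx = std::sqrt(6.0 / (C + 4.0 * H));
  double gh = std::sqrt(6.0 / (H + 4.0 * H));
  double gy = std::sqrt(6.0 / (H + C));
  p.Wx.set_size(C, 4 * H);
  p.Wh.set_size(H, 4 * H);
  p.Wy.set_size(H, C);
  for (auto& v : p.Wx) v = gx * unif(rng);
  for (auto& v : p.Wh) v = gh * unif(rng);
  for (auto& v : p.Wy) v = gy * unif(rng);
  p.b = rowvec(4 * H, fill::zeros);
  p.b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias at 1: standard init
  p.by = rowvec(C, fill::zeros);
  return p;
}

// Repack an R array dim (T, C, B) into per-time-step B x C matrices.
static std::vector<mat> slice_time(const cube& X) {
  const uword T = X.n_rows, C = X.n_cols, B = X.n_slices;
  std::vector<mat> out(T);
  for (uword t = 0; t < T; ++t) {
    mat m(B, C);
    for (uword b = 0; b < B; ++b)
      for (uword c = 0; c < C; ++c) m(b, c) = X(t, c, b);
    out[t] = std::move(m);
  }
  return out;
}

struct AdamState {
  mat mWx, vWx, mWh, vWh, mWy, vWy;
  rowvec mb, vb, mby, vby;
  int t = 0;
  explicit AdamState(const LSTMParams& p) {
    mWx = zeros(size(p.Wx)); vWx = mWx;
    mWh = zeros(size(p.Wh)); vWh = mWh;
    mWy = zeros(size(p.Wy)); vWy = mWy;
    mb = zeros<rowvec>(p.b.n_elem);  vb = mb;
    mby = zeros<rowvec>(p.by.n_elem); vby = mby;
  }
};

static void adam_step(mat& w, const mat& g, mat& m, mat& v, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  mat mhat = m / (1 - std::pow(b1, t));
  mat vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

static void adam_step(rowvec& w, const rowvec& g, rowvec& m, rowvec& v,
                      double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  rowvec mhat = m / (1 - std::pow(b1, t));
  rowvec vhat = v / (1 - std::pow(b2, t));
  w -= lr * mhat / (sqrt(vhat) + eps);
}

// One full-batch epoch: forward with dropout, BPTT, Adam update.
// Returns the data MSE (before the update, without the L2 penalty term).
static double train_epoch(LSTMParams& p, AdamState& adam,
                          const std::vector<mat>& Xt,
                          double lr, double dropout, double l2,
                          std::mt19937_64& rng) {
  const uword T = Xt.size(), B = Xt[0].n_rows, C = Xt[0].n_cols;
  const uword H = p.Wh.n_rows, S = T - 1;
  const double ntot = double(S) * B * C;

  cube Ig(B, H, S), Fg(B, H, S), Gg(B, H, S), Og(B, H, S);
  cube Cs(B, H, S), Hs(B, H, S), Mask(B, H, S), Err(B, C, S);

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double keep = 1.0 - dropout;

  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  double sse = 0.0;
  for (uword t = 0; t < S; ++t) {
    mat G = Xt[t] * p.Wx + h * p.Wh;
    G.each_row() += p.b;
    mat i = sigm(G.cols(0, H - 1));
    mat f = sigm(G.cols(H, 2 * H - 1));
    mat g = tanh(G.cols(2 * H, 3 * H - 1));
    mat o = sigm(G.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    mat mask(B, H);
    if (dropout > 0) {
      for (auto& v : mask) v = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    } else {
      mask.ones();
    }
    mat y = (h % mask) * p.Wy;
    y.each_row() += p.by;
    mat err = y - Xt[t + 1];
    sse += accu(square(err));
    Ig.slice(t) = i; Fg.slice(t) = f; Gg.slice(t) = g; Og.slice(t) = o;
    Cs.slice(t) = c; Hs.slice(t) = h; Mask.slice(t) = mask;
    Err.slice(t) = err;
  }

  mat dWx = zeros(size(p.Wx)), dWh = zeros(size(p.Wh)), dWy = zeros(size(p.Wy));
  rowvec db = zeros<rowvec>(p.b.n_elem), dby = zeros<rowvec>(p.by.n_elem);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);

  for (uword tt = S; tt-- > 0;) {
    const mat& i = Ig.slice(tt);
    const mat& f = Fg.slice(tt);
    const mat& g = Gg.slice(tt);
    const mat& o = Og.slice(tt);
    const mat& ct = Cs.slice(tt);
    const mat& ht = Hs.slice(tt);
    const mat& mask = Mask.slice(tt);
    mat derr = (2.0 / ntot) * Err.slice(tt);
    mat hd = ht % mask;
    dWy += hd.t() * derr;
    dby += sum(derr, 0);
    mat dh = (derr * p.Wy.t()) % mask + dh_next;
    mat tc = tanh(ct);
    mat do_ = dh % tc;
    mat dct = dh % o % (1.0 - square(tc)) + dc_next;
    mat cprev = (tt == 0) ? mat(B, H, fill::zeros) : Cs.slice(tt - 1);
    mat di = dct % g;
    mat df = dct % cprev;
    mat dg = dct % i;
    mat dG(B, 4 * H);
    dG.cols(0, H - 1)         = di % i % (1.0 - i);
    dG.cols(H, 2 * H - 1)     = df % f % (1.0 - f);
    dG.cols(2 * H, 3 * H - 1) = dg % (1.0 - square(g));
    dG.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dWx += Xt[tt].t() * dG;
    if (tt > 0) dWh += Hs.slice(tt - 1).t() * dG;
    db += sum(dG, 0);
    dh_next = dG * p.Wh.t();
    dc_next = dct % f;
  }
  dWx += 2.0 * l2 * p.Wx;  // kernel L2 penalty on the input weights

  ++adam.t;
  adam_step(p.Wx, dWx, adam.mWx, adam.vWx, lr, adam.t);
  adam_step(p.Wh, dWh, adam.mWh, adam.vWh, lr, adam.t);
  adam_step(p.Wy, dWy, adam.mWy, adam.vWy, lr, adam.t);
  adam_step(p.b,  db,  adam.mb,  adam.vb,  lr, adam.t);
  adam_step(p.by, dby, adam.mby, adam.vby, lr, adam.t);

  return sse / ntot;
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::cube& X, int hidden_units,
                          double learning_rate, double dropout_rate,
                          double l2_strength, int epochs, int patience,
                          double tol, int seed) {
  if (X.n_rows < 2) Rcpp::stop("sequences must have at least 2 time steps");
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<mat> Xt = slice_time(X);
  LSTMParams p = init_params(X.n_cols, hidden_units, rng);
  AdamState adam(p);

  std::vector<double> history;
  history.reserve(epochs);
  double best = datum::inf;
  int stall = 0;
  for (int e = 0; e < epochs; ++e) {
    double mse = train_epoch(p, adam, Xt, learning_rate, dropout_rate,
                             l2_strength, rng);
    if (!std::isfinite(mse))
      Rcpp::stop("non-finite training loss at epoch %d; lower the learning rate",
                 e + 1);
    history.push_back(mse);
    if (mse < best - tol) { best = mse; stall = 0; } else { ++stall; }
    if (patience > 0 && stall >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh,
      Rcpp::Named("b") = p.b, Rcpp::Named("Wy") = p.Wy,
      Rcpp::Named("by") = p.by,
      Rcpp::Named("loss_history") = history,
      Rcpp::Named("epochs_run") = (int)history.size());
}

// Deterministic inference pass (dropout disabled).  Returns the hidden state
// h_t and cell state c_t after consuming input rows 1..T-1, plus the linear
// readout y_t (the prediction of input row t+1) and the data MSE.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& Wx, const arma::mat& Wh,
                            const arma::rowvec& b, const arma::mat& Wy,
                            const arma::rowvec& by, const arma::mat& X) {
  const uword T = X.n_rows, C = X.n_cols, H = Wh.n_rows;
  if (T < 2) Rcpp::stop("sequence must have at least 2 time steps");
  const uword S = T - 1;
  mat Hs(S, H), Cs(S, H), Y(S, C);
  rowvec h(H, fill::zeros), c(H, fill::zeros);
  double sse = 0.0;
  for (uword t = 0; t < S; ++t) {
    rowvec G = X.row(t) * Wx + h * Wh + b;
    rowvec i = 1.0 / (1.0 + exp(-G.subvec(0, H - 1)));
    rowvec f = 1.0 / (1.0 + exp(-G.subvec(H, 2 * H - 1)));
    rowvec g = tanh(G.subvec(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + exp(-G.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    rowvec y = h * Wy + by;
    Hs.row(t) = h;
    Cs.row(t) = c;
    Y.row(t) = y;
    sse += accu(square(y - X.row(t + 1)));
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = Hs, Rcpp::Named("c") = Cs, Rcpp::Named("y") = Y,
      Rcpp::Named("mse") = sse / (double(S) * C));
}

// Objective (data MSE + L2 on Wx) over a batch of sequences, dropout off.
// Used by the finite-difference gradient check in the test suite.
// [[Rcpp::export]]
double lstm_loss_cpp(const arma::mat& Wx, const arma::mat& Wh,
                     const arma::rowvec& b, const arma::mat& Wy,
                     const arma::rowvec& by, const arma::cube& X,
                     double l2_strength) {
  std::vector<mat> Xt = slice_time(X);
  const uword T = Xt.size(), B = Xt[0].n_rows, C = Xt[0].n_cols;
  const uword H = Wh.n_rows, S = T - 1;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  double sse = 0.0;
  for (uword t = 0; t < S; ++t) {
    mat G = Xt[t] * Wx + h * Wh;
    G.each_row() += b;
    mat i = sigm(G.cols(0, H - 1));
    mat f = sigm(G.cols(H, 2 * H - 1));
    mat g = tanh(G.cols(2 * H, 3 * H - 1));
    mat o = sigm(G.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    mat y = (h * Wy);
    y.each_row() += by;
    sse += accu(square(y - Xt[t + 1]));
  }
  return sse / (double(S) * B * C) + l2_strength * accu(square(Wx));
}

// Analytic gradient of lstm_loss_cpp (dropout off), for the same check.
// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(const arma::mat& Wx, const arma::mat& Wh,
                         const arma::rowvec& b, const arma::mat& Wy,
                         const arma::rowvec& by, const arma::cube& X,
                         double l2_strength) {
  std::vector<mat> Xt = slice_time(X);
  LSTMParams p{Wx, Wh, Wy, b, by};
  AdamState adam(p);
  // run one epoch with lr 0 so parameters are untouched; recompute gradients
  // here instead: reuse train_epoch's machinery by copying its body would be
  // redundant, so call it with lr = 0 and a dummy rng, then recover gradients
  // via finite Adam state (m after one step equals 0.1 * grad).
  std::mt19937_64 rng(1);
  train_epoch(p, adam, Xt, 0.0, 0.0, l2_strength, rng);
  return Rcpp::List::create(
      Rcpp::Named("dWx") = adam.mWx / 0.1, Rcpp::Named("dWh") = adam.mWh / 0.1,
      Rcpp::Named("db") = adam.mb / 0.1, Rcpp::Named("dWy") = adam.mWy / 0.1,
      Rcpp::Named("dby") = adam.mby / 0.1);
}
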