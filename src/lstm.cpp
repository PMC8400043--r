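// LSTM cell, BPTT training with Adam, for:
//  - sequence-to-sequence flowrate regression (per-step scalar head)
//  - sequence-to-label pattern classification (softmax head on last h)
// Parameters are packed as Wg (4H x (H+D)) over the concatenation
// [h_{t-1}; x_t] with gate row blocks ordered i, f, g(candidate), o,
// biases b (4H), head Wy (K x H), by (K).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct Gates {
  cube I, F, G, O, C, TC, H; // H x B x T caches
};

// Forward pass for a batch of B equal-length sequences.
// X: D x B x T cube. Returns caches needed for BPTT.
static Gates forward_batch(const mat& Wg, const vec& b, const cube& X) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = Wg.n_rows / 4;
  Gates g;
  g.I.set_size(H, B, T); g.F.set_size(H, B, T); g.G.set_size(H, B, T);
  g.O.set_size(H, B, T); g.C.set_size(H, B, T); g.TC.set_size(H, B, T);
  g.H.set_size(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  mat v(H + D, B);
  for (uword t = 0; t < T; ++t) {
    v.rows(0, H - 1) = h;
    v.rows(H, H + D - 1) = X.slice(t);
    mat z = Wg * v;
    z.each_col() += b;
    mat i = sigmoid(z.rows(0, H - 1));
    mat f = sigmoid(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = sigmoid(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % gg;
    mat tc = tanh(c);
    h = o % tc;
    g.I.slice(t) = i; g.F.slice(t) = f; g.G.slice(t) = gg; g.O.slice(t) = o;
    g.C.slice(t) = c; g.TC.slice(t) = tc; g.H.slice(t) = h;
  }
  return g;
}

// Backward through the recurrence given dH (H x B x T) of loss wrt each h_t.
// Accumulates dWg, db; X as in forward.
static void backward_batch(const mat& Wg, const cube& X, const Gates& g,
                           const cube& dH, mat& dWg, vec& db) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = Wg.n_rows / 4;
  mat dh(H, B, fill::zeros), dc(H, B, fill::zeros);
  mat dz(4 * H, B), v(H + D, B);
  for (sword t = T - 1; t >= 0; --t) {
    dh += dH.slice(t);
    const mat& i = g.I.slice(t); const mat& f = g.F.slice(t);
    const mat& gg = g.G.slice(t); const mat& o = g.O.slice(t);
    const mat& tc = g.TC.slice(t);
    mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat c_prev = (t == 0) ? mat(H, B, fill::zeros) : g.C.slice(t - 1);
    mat di = dc % gg;
    mat dg = dc % i;
    mat df = dc % c_prev;
    mat dc_prev = dc % f;
    dz.rows(0, H - 1) = di % i % (1.0 - i);
    dz.rows(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.rows(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    v.rows(0, H - 1) = (t == 0) ? mat(H, B, fill::zeros) : g.H.slice(t - 1);
    v.rows(H, H + D - 1) = X.slice(t);
    dWg += dz * v.t();
    db += sum(dz, 1);
    mat dv = Wg.t() * dz;
    dh = dv.rows(0, H - 1);
    dc = dc_prev;
  }
}

struct Adam {
  mat mWg, vWg, mWy, vWy;
  vec mb, vb, mby, vby;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Adam(const mat& Wg, const vec& b, const mat& Wy, const vec& by)
      : mWg(size(Wg), fill::zeros), vWg(size(Wg), fill::zeros),
        mWy(size(Wy), fill::zeros), vWy(size(Wy), fill::zeros),
        mb(size(b), fill::zeros), vb(size(b), fill::zeros),
        mby(size(by), fill::zeros), vby(size(by), fill::zeros) {}

  template <class M>
  void upd(M& w, M& m, M& v, const M& gr, double lr) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }

  void step(mat& Wg, vec& b, mat& Wy, vec& by, const mat& dWg, const vec& db,
            const mat& dWy, const vec& dby, double lr) {
    ++t;
    upd(Wg, mWg, vWg, dWg, lr);
    upd(b, mb, vb, db, lr);
    upd(Wy, mWy, vWy, dWy, lr);
    upd(by, mby, vby, dby, lr);
  }
};

static void clip_grads(mat& dWg, vec& db, mat& dWy, vec& dby, double clip) {
  double n2 = accu(dWg % dWg) + accu(db % db) + accu(dWy % dWy) +
              accu(dby % dby);
  double nrm = std::sqrt(n2);
  if (clip > 0 && nrm > clip) {
    double s = clip / nrm;
    dWg *= s; db *= s; dWy *= s; dby *= s;
  }
}

// Deterministic Fisher-Yates shuffle with our own LCG-free PRNG.
static void shuffle_idx(std::vector<uword>& idx, std::mt19937& rng) {
  for (size_t k = idx.size(); k > 1; --k) {
    std::uniform_int_distribution<size_t> d(0, k - 1);
    std::swap(idx[k - 1], idx[d(rng)]);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::mat& Wg, const arma::vec& b,
                            const arma::mat& X) {
  // X: T x D (single sequence). Returns H, C as T x hidden matrices.
  const uword T = X.n_rows, D = X.n_cols;
  cube Xc(D, 1, T);
  for (uword t = 0; t < T; ++t) Xc.slice(t) = X.row(t).t();
  Gates g = forward_batch(Wg, b, Xc);
  const uword H = Wg.n_rows / 4;
  mat Hm(T, H), Cm(T, H);
  for (uword t = 0; t < T; ++t) {
    Hm.row(t) = g.H.slice(t).col(0).t();
    Cm.row(t) = g.C.slice(t).col(0).t();
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hm, Rcpp::Named("c") = Cm);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_regressor(const Rcpp::List& xs, const Rcpp::List& ys,
                               arma::mat Wg, arma::vec b, arma::mat Wy,
                               arma::vec by, int epochs, int batch_size,
                               double lr, double clip, int seed) {
  const uword n = xs.size();
  const uword H = Wg.n_rows / 4;
  std::vector<mat> X(n);
  std::vector<vec> Y(n);
  for (uword i = 0; i < n; ++i) {
    X[i] = Rcpp::as<mat>(xs[i]);
    Y[i] = Rcpp::as<vec>(ys[i]);
  }
  Adam opt(Wg, b, Wy, by);
  std::mt19937 rng(seed);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  vec losses(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_idx(idx, rng);
    double ep_loss = 0;
    uword pos = 0;
    while (pos < n) {
      uword bsz = std::min<uword>(batch_size, n - pos);
      mat dWg(size(Wg), fill::zeros), dWy(size(Wy), fill::zeros);
      vec db(size(b), fill::zeros), dby(size(by), fill::zeros);
      double batch_loss = 0;
      for (uword bi = 0; bi < bsz; ++bi) {
        const mat& x = X[idx[pos + bi]];
        const vec& y = Y[idx[pos + bi]];
        const uword T = x.n_rows, D = x.n_cols;
        cube Xc(D, 1, T);
        for (uword t = 0; t < T; ++t) Xc.slice(t) = x.row(t).t();
        Gates g = forward_batch(Wg, b, Xc);
        // per-step scalar head
        vec pred(T), dh_head(T);
        cube dH(H, 1, T);
        for (uword t = 0; t < T; ++t) {
          pred(t) = as_scalar(Wy * g.H.slice(t).col(0)) + by(0);
        }
        vec err = pred - y;
        batch_loss += mean(err % err);
        // d(mse)/d(pred) = 2 err / T, averaged over batch later
        for (uword t = 0; t < T; ++t) {
          double dy = 2.0 * err(t) / (double)T / (double)bsz;
          dH.slice(t) = Wy.t() * dy;
          dWy += dy * g.H.slice(t).col(0).t();
          dby(0) += dy;
        }
        backward_batch(Wg, Xc, g, dH, dWg, db);
      }
      clip_grads(dWg, db, dWy, dby, clip);
      opt.step(Wg, b, Wy, by, dWg, db, dWy, dby, lr);
      ep_loss += batch_loss / bsz;
      pos += bsz;
    }
    losses(ep) = ep_loss / std::ceil((double)n / batch_size);
  }
  return Rcpp::List::create(
      Rcpp::Named("Wg") = Wg, Rcpp::Named("b") = b, Rcpp::Named("Wy") = Wy,
      Rcpp::Named("by") = by, Rcpp::Named("loss") = losses);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_classifier(const arma::mat& X, const arma::ivec& labels,
                                arma::mat Wg, arma::vec b, arma::mat Wy,
                                arma::vec by, int epochs, int batch_size,
                                double lr, double clip, int seed) {
  // X: n x T (input dimension 1); labels in 0..K-1.
  const uword n = X.n_rows, T = X.n_cols;
  const uword H = Wg.n_rows / 4, K = Wy.n_rows;
  Adam opt(Wg, b, Wy, by);
  std::mt19937 rng(seed);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  vec losses(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_idx(idx, rng);
    double ep_loss = 0;
    uword pos = 0;
    uword n_batches = 0;
    while (pos < n) {
      uword bsz = std::min<uword>(batch_size, n - pos);
      cube Xc(1, bsz, T);
      for (uword bi = 0; bi < bsz; ++bi)
        for (uword t = 0; t < T; ++t) Xc(0, bi, t) = X(idx[pos + bi], t);
      Gates g = forward_batch(Wg, b, Xc);
      mat hT = g.H.slice(T - 1); // H x B
      mat logits = Wy * hT;      // K x B
      logits.each_col() += by;
      mat ex = exp(logits.each_row() - max(logits, 0));
      mat probs = ex.each_row() / sum(ex, 0);
      double batch_loss = 0;
      mat dlogits = probs;
      for (uword bi = 0; bi < bsz; ++bi) {
        uword y = labels(idx[pos + bi]);
        batch_loss += -std::log(std::max(probs(y, bi), 1e-12));
        dlogits(y, bi) -= 1.0;
      }
      dlogits /= (double)bsz;
      mat dWy = dlogits * hT.t();
      vec dby = sum(dlogits, 1);
      cube dH(H, bsz, T, fill::zeros);
      dH.slice(T - 1) = Wy.t() * dlogits;
      mat dWg(size(Wg), fill::zeros);
      vec db(size(b), fill::zeros);
      backward_batch(Wg, Xc, g, dH, dWg, db);
      clip_grads(dWg, db, dWy, dby, clip);
      opt.step(Wg, b, Wy, by, dWg, db, dWy, dby, lr);
      ep_loss += batch_loss / bsz;
      ++n_batches;
      pos += bsz;
    }
    losses(ep) = ep_loss / n_batches;
    (void)K;
  }
  return Rcpp::List::create(
      Rcpp::Named("Wg") = Wg, Rcpp::Named("b") = b, Rcpp::Named("Wy") = Wy,
      Rcpp::Named("by") = by, Rcpp::Named("loss") = losses);
}
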