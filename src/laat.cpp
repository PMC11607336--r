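// Bidirectional-LSTM label-attention multilabel classifier.
//
// Forward pass per note: embedding lookup, forward + backward LSTM,
// per-label attention over the concatenated hidden states, one sigmoid
// output per label.  Training minimizes summed per-label binary
// cross-entropy by backpropagation through time with Adam updates.
//
// All randomness (parameter init, epoch shuffling) is supplied by the R
// caller, so results are reproducible across platforms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Params {
  mat E;                  // V x d embedding
  mat Wxf, Whf; vec bf;   // forward LSTM: 4u x d, 4u x u, 4u
  mat Wxb, Whb; vec bb;   // backward LSTM
  mat W;                  // da x 2u attention projection
  mat U;                  // da x L attention scoring
  mat O; vec bo;          // L x 2u output weights, L biases
};

static Params params_from_list(const Rcpp::List& p) {
  Params out;
  out.E = Rcpp::as<mat>(p["E"]);
  out.Wxf = Rcpp::as<mat>(p["Wxf"]); out.Whf = Rcpp::as<mat>(p["Whf"]);
  out.bf = Rcpp::as<vec>(p["bf"]);
  out.Wxb = Rcpp::as<mat>(p["Wxb"]); out.Whb = Rcpp::as<mat>(p["Whb"]);
  out.bb = Rcpp::as<vec>(p["bb"]);
  out.W = Rcpp::as<mat>(p["W"]); out.U = Rcpp::as<mat>(p["U"]);
  out.O = Rcpp::as<mat>(p["O"]); out.bo = Rcpp::as<vec>(p["bo"]);
  return out;
}

static Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("E") = p.E,
    Rcpp::Named("Wxf") = p.Wxf, Rcpp::Named("Whf") = p.Whf,
    Rcpp::Named("bf") = p.bf,
    Rcpp::Named("Wxb") = p.Wxb, Rcpp::Named("Whb") = p.Whb,
    Rcpp::Named("bb") = p.bb,
    Rcpp::Named("W") = p.W, Rcpp::Named("U") = p.U,
    Rcpp::Named("O") = p.O, Rcpp::Named("bo") = p.bo);
}

static inline vec sigmoid_v(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// Per-direction LSTM caches for BPTT.
struct LstmCache {
  mat i, f, o, g, c, h;  // each u x T
};

// Run one LSTM direction over the embedded sequence X (d x T).
// If reverse, iterate t = T-1 .. 0 but store at column t.  The input
// projection Wx * X is hoisted into a single GEMM.
static void lstm_forward(const mat& X, const mat& Wx, const mat& Wh,
                         const vec& b, bool reverse, LstmCache& cc) {
  const uword T = X.n_cols;
  const uword u = Wh.n_cols;
  cc.i.set_size(u, T); cc.f.set_size(u, T); cc.o.set_size(u, T);
  cc.g.set_size(u, T); cc.c.set_size(u, T); cc.h.set_size(u, T);
  mat A0 = Wx * X;
  A0.each_col() += b;
  vec h = zeros<vec>(u), c = zeros<vec>(u), a(4 * u);
  for (uword k = 0; k < T; ++k) {
    uword t = reverse ? (T - 1 - k) : k;
    a = A0.col(t) + Wh * h;
    vec ig = sigmoid_v(a.subvec(0, u - 1));
    vec fg = sigmoid_v(a.subvec(u, 2 * u - 1));
    vec og = sigmoid_v(a.subvec(2 * u, 3 * u - 1));
    vec gg = tanh(a.subvec(3 * u, 4 * u - 1));
    c = fg % c + ig % gg;
    h = og % tanh(c);
    cc.i.col(t) = ig; cc.f.col(t) = fg; cc.o.col(t) = og; cc.g.col(t) = gg;
    cc.c.col(t) = c;  cc.h.col(t) = h;
  }
}

// BPTT for one direction.  dH (u x T) is the gradient w.r.t. this
// direction's hidden states.  Accumulates parameter grads and dX.
static void lstm_backward(const mat& X, const mat& Wx, const mat& Wh,
                          const LstmCache& cc, const mat& dH, bool reverse,
                          mat& dWx, mat& dWh, vec& db, mat& dX) {
  const uword T = X.n_cols;
  const uword u = Wh.n_cols;
  vec dh_rec = zeros<vec>(u), dc_rec = zeros<vec>(u);
  mat dA(4 * u, T);  // pre-activation gate grads; folded into GEMMs below
  for (uword k = 0; k < T; ++k) {
    // walk opposite to the forward order
    uword t = reverse ? k : (T - 1 - k);
    bool has_prev = reverse ? (t + 1 < T) : (t > 0);
    uword tp = reverse ? t + 1 : (t > 0 ? t - 1 : 0);

    vec dh = dH.col(t) + dh_rec;
    vec tc = tanh(cc.c.col(t));
    vec do_ = dh % tc;
    vec dc = dc_rec + dh % cc.o.col(t) % (1.0 - tc % tc);
    vec di = dc % cc.g.col(t);
    vec dg = dc % cc.i.col(t);

    dA.submat(0, t, u - 1, t) = di % cc.i.col(t) % (1.0 - cc.i.col(t));
    if (has_prev) {
      dA.submat(u, t, 2 * u - 1, t) =
        (dc % cc.c.col(tp)) % cc.f.col(t) % (1.0 - cc.f.col(t));
    } else {
      dA.submat(u, t, 2 * u - 1, t).zeros();  // c_prev = 0
    }
    dA.submat(2 * u, t, 3 * u - 1, t) =
      do_ % cc.o.col(t) % (1.0 - cc.o.col(t));
    dA.submat(3 * u, t, 4 * u - 1, t) =
      dg % (1.0 - cc.g.col(t) % cc.g.col(t));
    if (has_prev) {
      dWh += dA.col(t) * cc.h.col(tp).t();  // h_prev = 0 otherwise
    }
    dh_rec = Wh.t() * dA.col(t);
    dc_rec = dc % cc.f.col(t);
  }
  dWx += dA * X.t();
  db += sum(dA, 1);
  dX += Wx.t() * dA;
}

struct ForwardCache {
  mat X;           // d x T embedded inputs
  LstmCache fw, bw;
  mat H;           // 2u x T
  mat Z;           // da x T
  mat A;           // L x T attention weights
  mat Vdoc;        // 2u x L
  vec p;           // L predicted probabilities
};

static void forward_doc(const Params& P, const ivec& ids, ForwardCache& fc) {
  const uword T = ids.n_elem;
  const uword d = P.E.n_cols;
  const uword u = P.Whf.n_cols;
  const uword L = P.U.n_cols;
  fc.X.set_size(d, T);
  for (uword t = 0; t < T; ++t) fc.X.col(t) = P.E.row(ids[t] - 1).t();
  lstm_forward(fc.X, P.Wxf, P.Whf, P.bf, false, fc.fw);
  lstm_forward(fc.X, P.Wxb, P.Whb, P.bb, true, fc.bw);
  fc.H = join_cols(fc.fw.h, fc.bw.h);          // 2u x T
  fc.Z = tanh(P.W * fc.H);                     // da x T
  mat S = P.U.t() * fc.Z;                      // L x T scores
  fc.A.set_size(L, T);
  for (uword l = 0; l < L; ++l) {
    rowvec s = S.row(l);
    s -= s.max();
    rowvec e = exp(s);
    fc.A.row(l) = e / accu(e);
  }
  fc.Vdoc = fc.H * fc.A.t();                   // 2u x L
  vec logits(L);
  for (uword l = 0; l < L; ++l) {
    logits[l] = dot(P.O.row(l), fc.Vdoc.col(l)) + P.bo[l];
  }
  fc.p = sigmoid_v(logits);
  (void)u;
}

static double bce_loss(const vec& p, const vec& y) {
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  return -accu(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

// Backward pass for one note; accumulates into the gradient set G.
static void backward_doc(const Params& P, const ivec& ids,
                         const ForwardCache& fc, const vec& y, Params& G) {
  const uword T = ids.n_elem;
  const uword u = P.Whf.n_cols;
  const uword L = P.U.n_cols;

  vec dlogit = fc.p - y;                       // L
  for (uword l = 0; l < L; ++l) {
    G.O.row(l) += dlogit[l] * fc.Vdoc.col(l).t();
    G.bo[l] += dlogit[l];
  }
  mat dVdoc(2 * u, L);
  for (uword l = 0; l < L; ++l) dVdoc.col(l) = dlogit[l] * P.O.row(l).t();

  mat dA = dVdoc.t() * fc.H;                   // L x T
  mat dH = dVdoc * fc.A;                       // 2u x T
  mat dS(L, T);
  for (uword l = 0; l < L; ++l) {
    double inner = dot(fc.A.row(l), dA.row(l));
    dS.row(l) = fc.A.row(l) % (dA.row(l) - inner);
  }
  mat dZ = P.U * dS;                           // da x T
  G.U += fc.Z * dS.t();
  mat dZpre = dZ % (1.0 - fc.Z % fc.Z);
  G.W += dZpre * fc.H.t();
  dH += P.W.t() * dZpre;

  mat dX = zeros<mat>(fc.X.n_rows, T);
  lstm_backward(fc.X, P.Wxf, P.Whf, fc.fw, dH.rows(0, u - 1), false,
                G.Wxf, G.Whf, G.bf, dX);
  lstm_backward(fc.X, P.Wxb, P.Whb, fc.bw, dH.rows(u, 2 * u - 1), true,
                G.Wxb, G.Whb, G.bb, dX);
  for (uword t = 0; t < T; ++t) G.E.row(ids[t] - 1) += dX.col(t).t();
}

static Params zeros_like(const Params& P) {
  Params G;
  G.E = zeros<mat>(size(P.E));
  G.Wxf = zeros<mat>(size(P.Wxf)); G.Whf = zeros<mat>(size(P.Whf));
  G.bf = zeros<vec>(P.bf.n_elem);
  G.Wxb = zeros<mat>(size(P.Wxb)); G.Whb = zeros<mat>(size(P.Whb));
  G.bb = zeros<vec>(P.bb.n_elem);
  G.W = zeros<mat>(size(P.W)); G.U = zeros<mat>(size(P.U));
  G.O = zeros<mat>(size(P.O)); G.bo = zeros<vec>(P.bo.n_elem);
  return G;
}

// Adam update applied in-place to one parameter block.
static void adam_step(mat& w, const mat& g, mat& m, mat& v,
                      double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  mat mh = m / (1.0 - std::pow(b1, t));
  mat vh = v / (1.0 - std::pow(b2, t));
  w -= lr * mh / (sqrt(vh) + eps);
}
static void adam_step_v(vec& w, const vec& g, vec& m, vec& v,
                        double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  vec mh = m / (1.0 - std::pow(b1, t));
  vec vh = v / (1.0 - std::pow(b2, t));
  w -= lr * mh / (sqrt(vh) + eps);
}

static std::vector<ivec> docs_from_list(const Rcpp::List& docs) {
  std::vector<ivec> out(docs.size());
  for (R_xlen_t i = 0; i < docs.size(); ++i) {
    out[i] = Rcpp::as<ivec>(docs[i]);
  }
  return out;
}

// [[Rcpp::export(name = ".laat_predict_cpp")]]
arma::mat laat_predict_cpp(Rcpp::List params, Rcpp::List docs) {
  Params P = params_from_list(params);
  std::vector<ivec> D = docs_from_list(docs);
  mat out(D.size(), P.U.n_cols);
  ForwardCache fc;
  for (size_t i = 0; i < D.size(); ++i) {
    forward_doc(P, D[i], fc);
    out.row(i) = fc.p.t();
  }
  return out;
}

// [[Rcpp::export(name = ".laat_hidden_cpp")]]
arma::mat laat_hidden_cpp(Rcpp::List params, arma::ivec ids) {
  Params P = params_from_list(params);
  ForwardCache fc;
  forward_doc(P, ids, fc);
  return fc.H.t();  // T x 2u
}

// Loss and gradients for one note: the numerical-gradient test hook.
// [[Rcpp::export(name = ".laat_loss_grad_cpp")]]
Rcpp::List laat_loss_grad_cpp(Rcpp::List params, arma::ivec ids,
                              arma::vec y) {
  Params P = params_from_list(params);
  ForwardCache fc;
  forward_doc(P, ids, fc);
  Params G = zeros_like(P);
  backward_doc(P, ids, fc, y, G);
  return Rcpp::List::create(
    Rcpp::Named("loss") = bce_loss(fc.p, y),
    Rcpp::Named("grads") = params_to_list(G));
}

static double micro_f1(const mat& prob, const mat& y, double thr) {
  double tp = 0, fp = 0, fn = 0;
  for (uword i = 0; i < prob.n_rows; ++i) {
    for (uword j = 0; j < prob.n_cols; ++j) {
      bool pred = prob(i, j) >= thr;
      bool truth = y(i, j) > 0.5;
      if (pred && truth) tp++;
      else if (pred && !truth) fp++;
      else if (!pred && truth) fn++;
    }
  }
  double denom = 2 * tp + fp + fn;
  return denom == 0 ? 0.0 : 2 * tp / denom;
}

// Full training loop.  perms: epochs x n matrix of 1-based note orders
// (computed in R from the seed).  patience 0 disables early stopping.
// [[Rcpp::export(name = ".laat_train_cpp")]]
Rcpp::List laat_train_cpp(Rcpp::List params, Rcpp::List docs,
                          arma::mat y, Rcpp::List val_docs,
                          arma::mat val_y, arma::imat perms,
                          int epochs, int batch_size, double lr,
                          double threshold, int patience) {
  Params P = params_from_list(params);
  std::vector<ivec> D = docs_from_list(docs);
  std::vector<ivec> VD = docs_from_list(val_docs);
  const size_t n = D.size();

  Params M = zeros_like(P), V = zeros_like(P);
  double adam_t = 0;
  std::vector<double> epoch_loss, epoch_val_f1;
  Params best = P;
  double best_f1 = -1.0;
  int best_epoch = 0, since_best = 0;
  ForwardCache fc;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0;
    size_t pos = 0;
    while (pos < n) {
      size_t bend = std::min(pos + (size_t)batch_size, n);
      Params G = zeros_like(P);
      for (size_t k = pos; k < bend; ++k) {
        int idx = perms(ep, k) - 1;
        forward_doc(P, D[idx], fc);
        loss_sum += bce_loss(fc.p, y.row(idx).t());
        backward_doc(P, D[idx], fc, y.row(idx).t(), G);
      }
      double bs = (double)(bend - pos);
      adam_t += 1.0;
      adam_step(P.E, G.E / bs, M.E, V.E, lr, adam_t);
      adam_step(P.Wxf, G.Wxf / bs, M.Wxf, V.Wxf, lr, adam_t);
      adam_step(P.Whf, G.Whf / bs, M.Whf, V.Whf, lr, adam_t);
      adam_step_v(P.bf, G.bf / bs, M.bf, V.bf, lr, adam_t);
      adam_step(P.Wxb, G.Wxb / bs, M.Wxb, V.Wxb, lr, adam_t);
      adam_step(P.Whb, G.Whb / bs, M.Whb, V.Whb, lr, adam_t);
      adam_step_v(P.bb, G.bb / bs, M.bb, V.bb, lr, adam_t);
      adam_step(P.W, G.W / bs, M.W, V.W, lr, adam_t);
      adam_step(P.U, G.U / bs, M.U, V.U, lr, adam_t);
      adam_step(P.O, G.O / bs, M.O, V.O, lr, adam_t);
      adam_step_v(P.bo, G.bo / bs, M.bo, V.bo, lr, adam_t);
      pos = bend;
    }
    epoch_loss.push_back(loss_sum / (double)n);

    // validation micro-F1
    mat vp(VD.size(), P.U.n_cols);
    for (size_t i = 0; i < VD.size(); ++i) {
      forward_doc(P, VD[i], fc);
      vp.row(i) = fc.p.t();
    }
    double f1 = micro_f1(vp, val_y, threshold);
    epoch_val_f1.push_back(f1);

    if (patience > 0) {
      if (f1 > best_f1 + 1e-12) {
        best_f1 = f1;
        best = P;
        best_epoch = ep + 1;
        since_best = 0;
      } else if (++since_best >= patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  if (patience > 0 && best_f1 >= 0) {
    P = best;
  } else {
    best_epoch = (int)epoch_loss.size();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(P),
    Rcpp::Named("epoch_loss") = epoch_loss,
    Rcpp::Named("epoch_val_f1") = epoch_val_f1,
    Rcpp::Named("best_epoch") = best_epoch);
}
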