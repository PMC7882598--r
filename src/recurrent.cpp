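// Bidirectional recurrent sequence regressor (LSTM / GRU) with a learned
// categorical embedding channel, written for CPU training on modest block
// counts. Sequences are variable-length; padded steps are masked so the
// recurrent state is carried unchanged through them. All randomness
// (initialization, shuffling, recurrent dropout) flows from one seed, so a
// fixed seed gives repeatable training on a single thread.
//
// Layout note: a batch of N sequences over T steps is stored "stacked" as a
// D x (T*N) matrix (step t occupies columns [t*N, (t+1)*N)). Input-side
// products W * X are then single large GEMMs hoisted out of the timestep
// loop; only the recurrent products U * h remain per step.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NetSpec {
  int cell;      // 0 = lstm, 1 = gru
  int F;         // numeric features per step
  int H;         // hidden units per direction
  int E;         // embedding dimension (0 = no embedding channel)
  int V;         // embedding vocabulary (index 0 = PAD)
  int gates() const { return cell == 0 ? 4 : 3; }
  int D1() const { return F + E; }
  int D2() const { return 2 * H; }
  bool embed() const { return E > 0; }
};

// Parameter vector layout: [emb?] then per (layer, direction) W, U, b,
// then the regression head w, b0.
std::vector<mat> init_params(const NetSpec& sp, std::mt19937_64& rng) {
  auto glorot = [&](int r, int c) {
    double s = std::sqrt(6.0 / (r + c));
    std::uniform_real_distribution<double> u(-s, s);
    mat m(r, c);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(rng);
    return m;
  };
  std::vector<mat> p;
  if (sp.embed()) {
    std::normal_distribution<double> nd(0.0, 0.05);
    mat emb(sp.V, sp.E);
    for (uword j = 0; j < emb.n_cols; ++j)
      for (uword i = 0; i < emb.n_rows; ++i) emb(i, j) = nd(rng);
    emb.row(0).zeros();  // PAD
    p.push_back(emb);
  }
  int G = sp.gates();
  for (int layer = 0; layer < 2; ++layer) {
    int D = layer == 0 ? sp.D1() : sp.D2();
    for (int dir = 0; dir < 2; ++dir) {
      p.push_back(glorot(G * sp.H, D));
      p.push_back(glorot(G * sp.H, sp.H));
      mat b(G * sp.H, 1, fill::zeros);
      if (sp.cell == 0) b.rows(sp.H, 2 * sp.H - 1).fill(1.0);  // forget bias
      p.push_back(b);
    }
  }
  p.push_back(glorot(sp.D2(), 1));      // head weights
  p.push_back(mat(1, 1, fill::zeros));  // head bias
  return p;
}

inline int par_base(const NetSpec& sp, int layer, int dir) {
  return (sp.embed() ? 1 : 0) + 6 * layer + 3 * dir;
}

struct DirCache {
  // per processed step (natural time index t): caches for backprop
  std::vector<mat> h_prev;  // state entering the step
  std::vector<mat> c_prev;  // lstm only
  std::vector<mat> g1, g2, g3, g4;  // lstm: i,f,g,o ; gru: z,r,n
  std::vector<mat> c_cand;  // lstm only
  std::vector<mat> h;       // post-mask state at step t
  mat h_final;              // state after the last processed step
  mat drop;                 // recurrent dropout mask (H x N), ones if off
};

// One direction of one layer over a stacked input X (D x T*N).
// dir = +1 processes t = 0..T-1, dir = -1 processes t = T-1..0.
DirCache run_dir(const NetSpec& sp, const mat& X, const mat& M,
                 int dirsign, const mat& W, const mat& U, const mat& b,
                 const mat& drop) {
  int T = M.n_rows;
  int N = M.n_cols;
  int H = sp.H;
  DirCache cc;
  cc.h_prev.resize(T); cc.h.resize(T);
  cc.g1.resize(T); cc.g2.resize(T); cc.g3.resize(T);
  if (sp.cell == 0) { cc.g4.resize(T); cc.c_prev.resize(T); cc.c_cand.resize(T); }
  cc.drop = drop;
  mat WX = W * X;           // hoisted input-side product
  WX.each_col() += b.col(0);
  mat h(H, N, fill::zeros), c(H, N, fill::zeros);
  for (int k = 0; k < T; ++k) {
    int t = dirsign > 0 ? k : T - 1 - k;
    mat mk = repmat(M.row(t), H, 1);
    mat hd = drop % h;
    cc.h_prev[t] = h;
    if (sp.cell == 0) {
      cc.c_prev[t] = c;
      mat A = WX.cols(t * N, (t + 1) * N - 1) + U * hd;
      mat gi = 1.0 / (1.0 + exp(-A.rows(0, H - 1)));
      mat gf = 1.0 / (1.0 + exp(-A.rows(H, 2 * H - 1)));
      mat gg = tanh(A.rows(2 * H, 3 * H - 1));
      mat go = 1.0 / (1.0 + exp(-A.rows(3 * H, 4 * H - 1)));
      mat ccand = gf % c + gi % gg;
      mat hcand = go % tanh(ccand);
      cc.g1[t] = gi; cc.g2[t] = gf; cc.g3[t] = gg; cc.g4[t] = go;
      cc.c_cand[t] = ccand;
      c = mk % ccand + (1.0 - mk) % c;
      h = mk % hcand + (1.0 - mk) % h;
    } else {
      mat A = WX.cols(t * N, (t + 1) * N - 1);
      A.rows(0, 2 * H - 1) += U.rows(0, 2 * H - 1) * hd;
      mat gz = 1.0 / (1.0 + exp(-A.rows(0, H - 1)));
      mat gr = 1.0 / (1.0 + exp(-A.rows(H, 2 * H - 1)));
      mat gn = tanh(A.rows(2 * H, 3 * H - 1) + U.rows(2 * H, 3 * H - 1) * (gr % hd));
      mat hcand = (1.0 - gz) % gn + gz % h;
      cc.g1[t] = gz; cc.g2[t] = gr; cc.g3[t] = gn;
      h = mk % hcand + (1.0 - mk) % h;
    }
    cc.h[t] = h;
  }
  cc.h_final = h;
  return cc;
}

// Backprop through one direction. d_hs[t] are gradients on the stored
// per-step states (may be empty), dh_final on the final state. Adds the
// input gradient into dX (stacked) and accumulates dW, dU, db.
void back_dir(const NetSpec& sp, const DirCache& cc, const mat& X,
              const mat& M, int dirsign, const mat& W, const mat& U,
              const std::vector<mat>& d_hs, const mat& dh_final,
              mat& dW, mat& dU, mat& db, mat& dX) {
  int T = M.n_rows;
  int N = M.n_cols;
  int H = sp.H;
  int G = sp.gates();
  dU.zeros(U.n_rows, U.n_cols);
  mat dAstack(G * H, T * N, fill::zeros);
  mat dh = dh_final;
  if (dh.n_elem == 0) dh.zeros(H, N);
  mat dc(H, N, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    int t = dirsign > 0 ? k : T - 1 - k;
    mat mk = repmat(M.row(t), H, 1);
    mat dh_tot = dh;
    if (!d_hs.empty() && d_hs[t].n_elem > 0) dh_tot += d_hs[t];
    mat dh_cand = mk % dh_tot;
    mat dh_prev = (1.0 - mk) % dh_tot;
    if (sp.cell == 0) {
      const mat &gi = cc.g1[t], &gf = cc.g2[t], &gg = cc.g3[t], &go = cc.g4[t];
      mat tc = tanh(cc.c_cand[t]);
      mat dcc = dh_cand % go % (1.0 - tc % tc) + mk % dc;
      mat dc_prev = (1.0 - mk) % dc + dcc % gf;
      mat dgo = dh_cand % tc;
      mat dgi = dcc % gg;
      mat dgg = dcc % gi;
      mat dgf = dcc % cc.c_prev[t];
      mat dA(4 * H, N);
      dA.rows(0, H - 1) = dgi % gi % (1.0 - gi);
      dA.rows(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
      dA.rows(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
      dA.rows(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
      mat hd = cc.drop % cc.h_prev[t];
      dAstack.cols(t * N, (t + 1) * N - 1) = dA;
      dU += dA * hd.t();
      dh = dh_prev + cc.drop % (U.t() * dA);
      dc = dc_prev;
    } else {
      const mat &gz = cc.g1[t], &gr = cc.g2[t], &gn = cc.g3[t];
      const mat& hp = cc.h_prev[t];
      mat hd = cc.drop % hp;
      mat dgz = dh_cand % (hp - gn);
      mat dgn = dh_cand % (1.0 - gz);
      mat dh_prev2 = dh_prev + dh_cand % gz;
      mat dan = dgn % (1.0 - gn % gn);
      mat Un = U.rows(2 * H, 3 * H - 1);
      mat drh = Un.t() * dan;          // grad wrt (r % hd)
      mat dgr = drh % hd;
      mat dA(3 * H, N);
      dA.rows(0, H - 1) = dgz % gz % (1.0 - gz);
      dA.rows(H, 2 * H - 1) = dgr % gr % (1.0 - gr);
      dA.rows(2 * H, 3 * H - 1) = dan;
      dAstack.cols(t * N, (t + 1) * N - 1) = dA;
      dU.rows(0, 2 * H - 1) += dA.rows(0, 2 * H - 1) * hd.t();
      dU.rows(2 * H, 3 * H - 1) += dan * (gr % hd).t();
      mat dhd = U.rows(0, 2 * H - 1).t() * dA.rows(0, 2 * H - 1) + gr % drh;
      dh = dh_prev2 + cc.drop % dhd;
    }
  }
  dW = dAstack * X.t();
  db = sum(dAstack, 1);
  dX += W.t() * dAstack;
}

struct BatchData {
  mat X;    // layer-1 stacked inputs, D1 x (T*N)
  mat M;    // T x N mask
  imat aoi; // T x N embedding indices (0-based); empty when no embedding
};

// Assemble stacked layer-1 inputs for a set of sequence indices.
BatchData make_batch(const NetSpec& sp, const cube& Xc, const imat& A,
                     const ivec& len, const uvec& idx,
                     const std::vector<mat>& par) {
  int T = Xc.n_cols;
  int N = idx.n_elem;
  BatchData bd;
  bd.M.zeros(T, N);
  bd.X.set_size(sp.D1(), T * N);
  if (sp.embed()) bd.aoi.set_size(T, N);
  for (int j = 0; j < N; ++j) {
    uword n = idx(j);
    const mat& sl = Xc.slice(n);  // F x T
    for (int t = 0; t < T; ++t) {
      if (t < len(n)) bd.M(t, j) = 1.0;
      bd.X.submat(0, t * N + j, sp.F - 1, t * N + j) = sl.col(t);
      if (sp.embed()) {
        int a = A(t, n);
        bd.aoi(t, j) = a;
        bd.X.submat(sp.F, t * N + j, sp.D1() - 1, t * N + j) = par[0].row(a).t();
      }
    }
  }
  return bd;
}

struct ForwardOut {
  DirCache l1f, l1b, l2f, l2b;
  mat Z;  // stacked layer-2 inputs, 2H x (T*N)
  rowvec pred;
};

ForwardOut forward_net(const NetSpec& sp, const BatchData& bd,
                       const std::vector<mat>& par, const mat& drop1f,
                       const mat& drop1b, const mat& drop2f, const mat& drop2b) {
  int T = bd.M.n_rows;
  int N = bd.M.n_cols;
  int H = sp.H;
  ForwardOut fo;
  int b1f = par_base(sp, 0, 0), b1b = par_base(sp, 0, 1);
  int b2f = par_base(sp, 1, 0), b2b = par_base(sp, 1, 1);
  fo.l1f = run_dir(sp, bd.X, bd.M, +1, par[b1f], par[b1f + 1], par[b1f + 2], drop1f);
  fo.l1b = run_dir(sp, bd.X, bd.M, -1, par[b1b], par[b1b + 1], par[b1b + 2], drop1b);
  fo.Z.set_size(2 * H, T * N);
  for (int t = 0; t < T; ++t) {
    fo.Z.submat(0, t * N, H - 1, (t + 1) * N - 1) = fo.l1f.h[t];
    fo.Z.submat(H, t * N, 2 * H - 1, (t + 1) * N - 1) = fo.l1b.h[t];
  }
  fo.l2f = run_dir(sp, fo.Z, bd.M, +1, par[b2f], par[b2f + 1], par[b2f + 2], drop2f);
  fo.l2b = run_dir(sp, fo.Z, bd.M, -1, par[b2b], par[b2b + 1], par[b2b + 2], drop2b);
  const mat& w = par[par.size() - 2];
  double b0 = par[par.size() - 1](0, 0);
  mat R = join_cols(fo.l2f.h_final, fo.l2b.h_final);
  fo.pred = w.col(0).t() * R;
  fo.pred += b0;
  return fo;
}

// Full backward pass; returns gradients in the same layout as the params.
std::vector<mat> backward_net(const NetSpec& sp, const BatchData& bd,
                              const std::vector<mat>& par, const ForwardOut& fo,
                              const rowvec& dpred) {
  int T = bd.M.n_rows;
  int N = bd.M.n_cols;
  int H = sp.H;
  std::vector<mat> g(par.size());
  if (sp.embed()) g[0].zeros(par[0].n_rows, par[0].n_cols);
  int b1f = par_base(sp, 0, 0), b1b = par_base(sp, 0, 1);
  int b2f = par_base(sp, 1, 0), b2b = par_base(sp, 1, 1);
  const mat& w = par[par.size() - 2];
  mat R = join_cols(fo.l2f.h_final, fo.l2b.h_final);
  g[par.size() - 2] = R * dpred.t();
  g[par.size() - 1] = mat(1, 1);
  g[par.size() - 1](0, 0) = accu(dpred);
  mat dR = w * dpred;  // 2H x N
  std::vector<mat> none;
  mat dZ(2 * H, T * N, fill::zeros);
  back_dir(sp, fo.l2f, fo.Z, bd.M, +1, par[b2f], par[b2f + 1], none,
           dR.rows(0, H - 1), g[b2f], g[b2f + 1], g[b2f + 2], dZ);
  back_dir(sp, fo.l2b, fo.Z, bd.M, -1, par[b2b], par[b2b + 1], none,
           dR.rows(H, 2 * H - 1), g[b2b], g[b2b + 1], g[b2b + 2], dZ);
  std::vector<mat> dh1f(T), dh1b(T);
  for (int t = 0; t < T; ++t) {
    dh1f[t] = dZ.submat(0, t * N, H - 1, (t + 1) * N - 1);
    dh1b[t] = dZ.submat(H, t * N, 2 * H - 1, (t + 1) * N - 1);
  }
  mat dX(sp.D1(), T * N, fill::zeros);
  mat empty;
  back_dir(sp, fo.l1f, bd.X, bd.M, +1, par[b1f], par[b1f + 1], dh1f, empty,
           g[b1f], g[b1f + 1], g[b1f + 2], dX);
  back_dir(sp, fo.l1b, bd.X, bd.M, -1, par[b1b], par[b1b + 1], dh1b, empty,
           g[b1b], g[b1b + 1], g[b1b + 2], dX);
  if (sp.embed()) {
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < N; ++j) {
        int a = bd.aoi(t, j);
        if (a > 0) {
          g[0].row(a) += dX.submat(sp.F, t * N + j, sp.D1() - 1, t * N + j).t();
        }
      }
  }
  return g;
}

mat ones_mask(int H, int N) { return mat(H, N, fill::ones); }

mat sample_drop(int H, int N, double rate, std::mt19937_64& rng) {
  if (rate <= 0.0) return ones_mask(H, N);
  std::bernoulli_distribution bern(1.0 - rate);
  mat m(H, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < H; ++i) m(i, j) = bern(rng) ? 1.0 / (1.0 - rate) : 0.0;
  return m;
}

NetSpec spec_from_opts(const Rcpp::List& opts, int F) {
  NetSpec sp;
  std::string cell = Rcpp::as<std::string>(opts["cell"]);
  sp.cell = (cell == "gru") ? 1 : 0;
  sp.F = F;
  sp.H = Rcpp::as<int>(opts["hidden"]);
  sp.E = Rcpp::as<int>(opts["embedding_dim"]);
  sp.V = Rcpp::as<int>(opts["vocab"]);
  if (!Rcpp::as<bool>(opts["use_embed"])) sp.E = 0;
  return sp;
}

std::vector<mat> params_from_list(const Rcpp::List& wl) {
  std::vector<mat> p;
  for (int i = 0; i < wl.size(); ++i) p.push_back(Rcpp::as<mat>(wl[i]));
  return p;
}

Rcpp::List params_to_list(const NetSpec& sp, const std::vector<mat>& p) {
  Rcpp::List out;
  std::vector<std::string> nm;
  if (sp.embed()) nm.push_back("emb");
  const char* layers[2] = {"1", "2"};
  const char* dirs[2] = {"f", "b"};
  for (int l = 0; l < 2; ++l)
    for (int d = 0; d < 2; ++d) {
      nm.push_back(std::string("W") + layers[l] + dirs[d]);
      nm.push_back(std::string("U") + layers[l] + dirs[d]);
      nm.push_back(std::string("b") + layers[l] + dirs[d]);
    }
  nm.push_back("w_out");
  nm.push_back("b_out");
  for (size_t i = 0; i < p.size(); ++i) out.push_back(Rcpp::wrap(p[i]));
  out.attr("names") = Rcpp::wrap(nm);
  return out;
}

rowvec predict_all(const NetSpec& sp, const cube& X, const imat& A,
                   const ivec& len, const std::vector<mat>& par, int chunk) {
  int N = X.n_slices;
  rowvec out(N);
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = regspace<uvec>(s, e - 1);
    BatchData bd = make_batch(sp, X, A, len, idx, par);
    int nb = idx.n_elem;
    ForwardOut fo = forward_net(sp, bd, par, ones_mask(sp.H, nb),
                                ones_mask(sp.H, nb), ones_mask(sp.H, nb),
                                ones_mask(sp.H, nb));
    out.subvec(s, e - 1) = fo.pred;
  }
  return out;
}

double mse_loss(const rowvec& pred, const rowvec& y) {
  rowvec r = pred - y;
  return accu(r % r) / r.n_elem;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(const arma::cube& Xtr, const arma::imat& Atr,
                         const arma::ivec& lentr, const arma::rowvec& ytr,
                         const arma::cube& Xval, const arma::imat& Aval,
                         const arma::ivec& lenval, const arma::rowvec& yval,
                         Rcpp::List opts) {
  NetSpec sp = spec_from_opts(opts, Xtr.n_rows);
  int epochs = Rcpp::as<int>(opts["epochs"]);
  int patience = Rcpp::as<int>(opts["patience"]);
  int batch = Rcpp::as<int>(opts["batch_size"]);
  double lr = Rcpp::as<double>(opts["learning_rate"]);
  double drop_rate = sp.cell == 0 ? Rcpp::as<double>(opts["recurrent_dropout"]) : 0.0;
  unsigned long seed = Rcpp::as<double>(opts["seed"]);
  std::mt19937_64 rng(seed);
  int Ntr = Xtr.n_slices;
  std::vector<mat> par = init_params(sp, rng);
  std::vector<mat> adam_m(par.size()), adam_v(par.size());
  for (size_t i = 0; i < par.size(); ++i) {
    adam_m[i].zeros(par[i].n_rows, par[i].n_cols);
    adam_v[i].zeros(par[i].n_rows, par[i].n_cols);
  }
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  std::vector<mat> best_par = par;
  int best_epoch = 0, wait = 0;
  std::vector<uword> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    long ep_n = 0;
    for (int s = 0; s < Ntr; s += batch) {
      int e = std::min(Ntr, s + batch);
      uvec idx(e - s);
      for (int j = s; j < e; ++j) idx(j - s) = order[j];
      int nb = idx.n_elem;
      BatchData bd = make_batch(sp, Xtr, Atr, lentr, idx, par);
      mat d1f = sample_drop(sp.H, nb, drop_rate, rng);
      mat d1b = sample_drop(sp.H, nb, drop_rate, rng);
      mat d2f = sample_drop(sp.H, nb, drop_rate, rng);
      mat d2b = sample_drop(sp.H, nb, drop_rate, rng);
      ForwardOut fo = forward_net(sp, bd, par, d1f, d1b, d2f, d2b);
      rowvec yb(nb);
      for (int j = 0; j < nb; ++j) yb(j) = ytr(idx(j));
      rowvec resid = fo.pred - yb;
      ep_loss += accu(resid % resid);
      ep_n += nb;
      rowvec dpred = 2.0 * resid / nb;
      std::vector<mat> g = backward_net(sp, bd, par, fo, dpred);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < par.size(); ++i) {
        adam_m[i] = beta1 * adam_m[i] + (1.0 - beta1) * g[i];
        adam_v[i] = beta2 * adam_v[i] + (1.0 - beta2) * (g[i] % g[i]);
        par[i] -= lr * (adam_m[i] / bc1) / (sqrt(adam_v[i] / bc2) + eps);
      }
      if (!par[0].is_finite()) Rcpp::stop("non-finite parameters during training (NaN loss?)");
    }
    double train_loss = ep_loss / ep_n;
    rowvec pv = predict_all(sp, Xval, Aval, lenval, par, 512);
    double val_loss = mse_loss(pv, yval);
    if (!std::isfinite(train_loss) || !std::isfinite(val_loss))
      Rcpp::stop("non-finite loss at epoch %d", ep + 1);
    hist_train.push_back(train_loss);
    hist_val.push_back(val_loss);
    if (val_loss < best_val - 1e-12) {
      best_val = val_loss;
      best_par = par;
      best_epoch = ep + 1;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    if ((ep & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(sp, best_par),
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::rowvec rnn_predict_cpp(Rcpp::List weights, const arma::cube& X,
                             const arma::imat& A, const arma::ivec& len,
                             Rcpp::List opts) {
  NetSpec sp = spec_from_opts(opts, X.n_rows);
  std::vector<mat> par = params_from_list(weights);
  return predict_all(sp, X, A, len, par, 512);
}

// Loss and analytic gradient on one full batch without dropout; used by the
// finite-difference gradient check in the test suite.
// [[Rcpp::export]]
Rcpp::List rnn_loss_grad_cpp(Rcpp::List weights, const arma::cube& X,
                             const arma::imat& A, const arma::ivec& len,
                             const arma::rowvec& y, Rcpp::List opts) {
  NetSpec sp = spec_from_opts(opts, X.n_rows);
  std::vector<mat> par = params_from_list(weights);
  int N = X.n_slices;
  uvec idx = regspace<uvec>(0, N - 1);
  BatchData bd = make_batch(sp, X, A, len, idx, par);
  ForwardOut fo = forward_net(sp, bd, par, ones_mask(sp.H, N), ones_mask(sp.H, N),
                              ones_mask(sp.H, N), ones_mask(sp.H, N));
  rowvec resid = fo.pred - y;
  double loss = accu(resid % resid) / N;
  rowvec dpred = 2.0 * resid / N;
  std::vector<mat> g = backward_net(sp, bd, par, fo, dpred);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(sp, g));
}

// [[Rcpp::export]]
Rcpp::List rnn_init_cpp(int n_features, Rcpp::List opts) {
  NetSpec sp = spec_from_opts(opts, n_features);
  unsigned long seed = Rcpp::as<double>(opts["seed"]);
  std::mt19937_64 rng(seed);
  std::vector<mat> par = init_params(sp, rng);
  return params_to_list(sp, par);
}
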