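// Stacked-LSTM binary stratifier: two LSTM layers over the ordered
// valid-feature sequence (one scalar per timestep), a sigmoid fully
// connected layer and a sigmoid output unit, trained with MSE loss and
// Adam. Training is fully deterministic given the initial weights and the
// shuffling seed (own Fisher-Yates on a mt19937 stream, so the order does
// not depend on the C++ standard library's distribution implementations).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube G;   // 4H x B x T, activated gates stacked [i; f; g; o]
  cube C;   // H x B x T, cell states
  cube Th;  // H x B x T, tanh(c)
  cube H;   // H x B x T, hidden states
};

struct Weights {
  mat W1, U1, b1, W2, U2, b2, Wd, bd, Wo, bo;
};

static Weights unpack(const List& w) {
  Weights p;
  p.W1 = Rcpp::as<mat>(w["W1"]); p.U1 = Rcpp::as<mat>(w["U1"]);
  p.b1 = Rcpp::as<mat>(w["b1"]); p.W2 = Rcpp::as<mat>(w["W2"]);
  p.U2 = Rcpp::as<mat>(w["U2"]); p.b2 = Rcpp::as<mat>(w["b2"]);
  p.Wd = Rcpp::as<mat>(w["Wd"]); p.bd = Rcpp::as<mat>(w["bd"]);
  p.Wo = Rcpp::as<mat>(w["Wo"]); p.bo = Rcpp::as<mat>(w["bo"]);
  return p;
}

static List pack(const Weights& p) {
  return List::create(
      Rcpp::Named("W1") = p.W1, Rcpp::Named("U1") = p.U1,
      Rcpp::Named("b1") = p.b1, Rcpp::Named("W2") = p.W2,
      Rcpp::Named("U2") = p.U2, Rcpp::Named("b2") = p.b2,
      Rcpp::Named("Wd") = p.Wd, Rcpp::Named("bd") = p.bd,
      Rcpp::Named("Wo") = p.Wo, Rcpp::Named("bo") = p.bo);
}

static void lstm_forward(const cube& In, const mat& W, const mat& U,
                         const mat& b, LstmCache& cc) {
  const uword H = U.n_rows / 4, B = In.n_cols, T = In.n_slices;
  cc.G.set_size(4 * H, B, T); cc.C.set_size(H, B, T);
  cc.Th.set_size(H, B, T); cc.H.set_size(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat z = W * In.slice(t) + U * h;
    z.each_col() += b.col(0);
    mat i = sigm(z.rows(0, H - 1));
    mat f = sigm(z.rows(H, 2 * H - 1));
    mat g = tanh(z.rows(2 * H, 3 * H - 1));
    mat o = sigm(z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat th = tanh(c);
    h = o % th;
    cc.G.slice(t) = join_cols(join_cols(i, f), join_cols(g, o));
    cc.C.slice(t) = c; cc.Th.slice(t) = th; cc.H.slice(t) = h;
  }
}

// Backprop through one layer; dH_ext holds upstream dL/dh_t. Fills dIn and
// parameter gradients (accumulated into zero-initialized outputs).
static void lstm_backward(const cube& In, const mat& W, const mat& U,
                          const LstmCache& cc, const cube& dH_ext,
                          mat& dW, mat& dU, mat& db, cube& dIn) {
  const uword H = U.n_rows / 4, B = In.n_cols, T = In.n_slices;
  dW.zeros(W.n_rows, W.n_cols); dU.zeros(U.n_rows, U.n_cols);
  db.zeros(4 * H, 1); dIn.set_size(size(In));
  mat dh_carry(H, B, fill::zeros), dc_carry(H, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& G = cc.G.slice(t);
    mat i = G.rows(0, H - 1), f = G.rows(H, 2 * H - 1);
    mat g = G.rows(2 * H, 3 * H - 1), o = G.rows(3 * H, 4 * H - 1);
    const mat& th = cc.Th.slice(t);
    mat c_prev = (t == 0) ? mat(H, B, fill::zeros) : cc.C.slice(t - 1);
    mat h_prev = (t == 0) ? mat(H, B, fill::zeros) : cc.H.slice(t - 1);
    mat dh = dH_ext.slice(t) + dh_carry;
    mat dc = dc_carry + dh % o % (1 - th % th);
    mat dzi = (dc % g) % i % (1 - i);
    mat dzf = (dc % c_prev) % f % (1 - f);
    mat dzg = (dc % i) % (1 - g % g);
    mat dzo = (dh % th) % o % (1 - o);
    mat dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
    dW += dz * In.slice(t).t();
    dU += dz * h_prev.t();
    db += sum(dz, 1);
    dIn.slice(t) = W.t() * dz;
    dh_carry = U.t() * dz;
    dc_carry = dc % f;
  }
}

// Forward pass for a batch (rows of X given by idx); returns probabilities
// and, if caches given, fills them plus the dense activations.
static rowvec net_forward(const mat& X, const uvec& idx, const Weights& p,
                          LstmCache& c1, LstmCache& c2, mat& a_fc,
                          cube& In1) {
  const uword B = idx.n_elem, T = X.n_cols;
  In1.set_size(1, B, T);
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < B; ++b) In1(0, b, t) = X(idx(b), t);
  lstm_forward(In1, p.W1, p.U1, p.b1, c1);
  lstm_forward(c1.H, p.W2, p.U2, p.b2, c2);
  mat h2T = c2.H.slice(T - 1);
  a_fc = sigm(p.Wd * h2T + repmat(p.bd, 1, B));
  mat out = sigm(p.Wo * a_fc + repmat(p.bo, 1, B));
  return out.row(0);
}

// MSE loss + full gradient for a batch. Returns loss; fills grads in gw.
static double net_backward(const mat& X, const uvec& idx, const vec& y,
                           const Weights& p, Weights& gw) {
  const uword B = idx.n_elem, T = X.n_cols;
  LstmCache c1, c2;
  mat a_fc; cube In1;
  rowvec prob = net_forward(X, idx, p, c1, c2, a_fc, In1);
  rowvec yy(B);
  for (uword b = 0; b < B; ++b) yy(b) = y(idx(b));
  rowvec err = prob - yy;
  double loss = accu(err % err) / B;
  rowvec dP = 2.0 * err / B;
  rowvec dzo = dP % prob % (1 - prob);
  gw.Wo = dzo * a_fc.t();
  gw.bo = mat(1, 1); gw.bo(0, 0) = accu(dzo);
  mat da = p.Wo.t() * dzo;
  mat dz1 = da % a_fc % (1 - a_fc);
  mat h2T = c2.H.slice(T - 1);
  gw.Wd = dz1 * h2T.t();
  gw.bd = sum(dz1, 1);
  cube dH2(c2.H.n_rows, B, T, fill::zeros);
  dH2.slice(T - 1) = p.Wd.t() * dz1;
  cube dIn2, dIn1;
  lstm_backward(c1.H, p.W2, p.U2, c2, dH2, gw.W2, gw.U2, gw.b2, dIn2);
  lstm_backward(In1, p.W1, p.U1, c1, dIn2, gw.W1, gw.U1, gw.b1, dIn1);
  return loss;
}

struct Adam {
  std::vector<mat> m, v;
  double b1, b2, eps, lr;
  long t = 0;
  void init(const std::vector<mat*>& ps, double lr_, double b1_, double b2_,
            double eps_) {
    lr = lr_; b1 = b1_; b2 = b2_; eps = eps_;
    for (auto* p : ps) {
      m.push_back(mat(size(*p), fill::zeros));
      v.push_back(mat(size(*p), fill::zeros));
    }
  }
  void step(std::vector<mat*>& ps, const std::vector<mat*>& gs) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    for (size_t k = 0; k < ps.size(); ++k) {
      m[k] = b1 * m[k] + (1 - b1) * (*gs[k]);
      v[k] = b2 * v[k] + (1 - b2) * square(*gs[k]);
      *ps[k] -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
    }
  }
};

static std::vector<mat*> param_ptrs(Weights& p) {
  return {&p.W1, &p.U1, &p.b1, &p.W2, &p.U2, &p.b2,
          &p.Wd, &p.bd, &p.Wo, &p.bo};
}

// [[Rcpp::export]]
List lstm_train_cpp(const arma::mat& X, const arma::vec& y, List w0,
                    int epochs, int batch, double lr, double beta1,
                    double beta2, double eps, int seed) {
  Weights p = unpack(w0);
  Weights g;
  std::vector<mat*> ps = param_ptrs(p), gs = param_ptrs(g);
  Adam opt;
  opt.init(ps, lr, beta1, beta2, eps);
  const uword n = X.n_rows;
  std::mt19937 rng((unsigned)seed);
  std::vector<uword> ord(n);
  for (uword i = 0; i < n; ++i) ord[i] = i;
  vec loss_hist(epochs), acc_hist(epochs);
  for (int e = 0; e < epochs; ++e) {
    for (uword i = n - 1; i > 0; --i) {  // Fisher-Yates
      uword j = rng() % (i + 1);
      std::swap(ord[i], ord[j]);
    }
    double eloss = 0; uword ncorrect = 0;
    for (uword start = 0; start < n; start += batch) {
      uword stop = std::min<uword>(start + batch, n);
      uvec idx(stop - start);
      for (uword k = start; k < stop; ++k) idx(k - start) = ord[k];
      double l = net_backward(X, idx, y, p, g);
      eloss += l * idx.n_elem;
      opt.step(ps, gs);
    }
    // end-of-epoch training accuracy on the full set
    LstmCache c1, c2; mat a; cube in1;
    uvec all = regspace<uvec>(0, n - 1);
    rowvec prob = net_forward(X, all, p, c1, c2, a, in1);
    for (uword i = 0; i < n; ++i)
      if ((prob(i) > 0.5) == (y(i) > 0.5)) ++ncorrect;
    loss_hist(e) = eloss / n;
    acc_hist(e) = (double)ncorrect / n;
    if (e % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Rcpp::Named("weights") = pack(p),
                      Rcpp::Named("loss") = loss_hist,
                      Rcpp::Named("accuracy") = acc_hist);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(const arma::mat& X, List w, int chunk = 512) {
  Weights p = unpack(w);
  const uword n = X.n_rows;
  vec out(n);
  for (uword start = 0; start < n; start += chunk) {
    uword stop = std::min<uword>(start + chunk, n);
    uvec idx = regspace<uvec>(start, stop - 1);
    LstmCache c1, c2; mat a; cube in1;
    rowvec prob = net_forward(X, idx, p, c1, c2, a, in1);
    out.subvec(start, stop - 1) = prob.t();
  }
  return out;
}

// [[Rcpp::export]]
List lstm_loss_grad_cpp(const arma::mat& X, const arma::vec& y, List w) {
  Weights p = unpack(w);
  Weights g;
  uvec all = regspace<uvec>(0, X.n_rows - 1);
  double loss = net_backward(X, all, y, p, g);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grad") = pack(g));
}
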