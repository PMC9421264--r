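// Stochastic-gradient core for the importance-weighted variational
// autoencoder IRT estimator.  All gradients are derived by hand:
//
//   decoder   P = c + (d - c) * sigmoid(A theta + b), masked Bernoulli
//   encoder   tanh MLP -> (mu, log sigma^2), theta = mu + sigma * e
//   ELBO      (1/S) sum_s loglik - kl_weight * KL(q || N(0,I))
//   IW-ELBO   logsumexp_r(v_r) - log R,  v = loglik + log p - log q
//
// In the IW stage the decoder gradient uses the normalized importance
// weights and the encoder gradient uses the doubly reparameterized
// (DReG) estimator: squared normalized weights times the pathwise
// derivative d v / d theta * d theta / d phi, with the variational
// parameters inside v treated as constants.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double P_EPS = 1e-7;    // likelihood clamp
static const double V_CLAMP = 1e6;   // last-resort log-weight clamp

struct Encoder {
  std::vector<mat> W;
  std::vector<vec> b;
  mat Wmu; vec bmu;
  mat Wlv; vec blv;
};

struct EncoderGrad {
  std::vector<mat> W;
  std::vector<vec> b;
  mat Wmu; vec bmu;
  mat Wlv; vec blv;
  void zero_like(const Encoder& e) {
    W.clear(); b.clear();
    for (size_t l = 0; l < e.W.size(); ++l) {
      W.push_back(zeros<mat>(e.W[l].n_rows, e.W[l].n_cols));
      b.push_back(zeros<vec>(e.b[l].n_elem));
    }
    Wmu = zeros<mat>(e.Wmu.n_rows, e.Wmu.n_cols);
    bmu = zeros<vec>(e.bmu.n_elem);
    Wlv = zeros<mat>(e.Wlv.n_rows, e.Wlv.n_cols);
    blv = zeros<vec>(e.blv.n_elem);
  }
};

static Encoder encoder_from_list(const List& enc) {
  Encoder e;
  List Ws = enc["W"], bs = enc["b"];
  for (int l = 0; l < Ws.size(); ++l) {
    e.W.push_back(as<mat>(Ws[l]));
    e.b.push_back(as<vec>(bs[l]));
  }
  e.Wmu = as<mat>(enc["W_mu"]);  e.bmu = as<vec>(enc["b_mu"]);
  e.Wlv = as<mat>(enc["W_lv"]);  e.blv = as<vec>(enc["b_lv"]);
  return e;
}

static List encoder_to_list(const Encoder& e) {
  List Ws(e.W.size()), bs(e.b.size());
  for (size_t l = 0; l < e.W.size(); ++l) { Ws[l] = e.W[l]; bs[l] = e.b[l]; }
  return List::create(_["W"] = Ws, _["b"] = bs,
                      _["W_mu"] = e.Wmu, _["b_mu"] = e.bmu,
                      _["W_lv"] = e.Wlv, _["b_lv"] = e.blv);
}

// Forward pass; Hs[0] is the input, Hs[l] the l-th hidden activation.
static void enc_forward(const Encoder& e, const mat& X,
                        std::vector<mat>& Hs, mat& mu, mat& lv) {
  Hs.clear();
  Hs.push_back(X);
  for (size_t l = 0; l < e.W.size(); ++l) {
    mat Z = Hs.back() * e.W[l].t();
    Z.each_row() += e.b[l].t();
    Hs.push_back(tanh(Z));
  }
  mu = Hs.back() * e.Wmu.t();
  mu.each_row() += e.bmu.t();
  lv = Hs.back() * e.Wlv.t();
  lv.each_row() += e.blv.t();
}

// Backprop head gradients (B x K) through the MLP into g.
static void enc_backward(const Encoder& e, const std::vector<mat>& Hs,
                         const mat& g_mu, const mat& g_lv, EncoderGrad& g) {
  g.Wmu += g_mu.t() * Hs.back();
  g.bmu += sum(g_mu, 0).t();
  g.Wlv += g_lv.t() * Hs.back();
  g.blv += sum(g_lv, 0).t();
  mat gH = g_mu * e.Wmu + g_lv * e.Wlv;
  for (int l = (int)e.W.size() - 1; l >= 0; --l) {
    mat gZ = gH % (1.0 - square(Hs[l + 1]));
    g.W[l] += gZ.t() * Hs[l];
    g.b[l] += sum(gZ, 0).t();
    if (l > 0) gH = gZ * e.W[l];
  }
}

struct DecoderGrad {
  mat A; vec b; vec c_raw; vec d_raw;
};

// One minibatch objective + gradients.
// mode 1: ELBO with S Monte Carlo samples (R must be 1), KL weight kl_w.
// mode 2: IW-ELBO with S groups of R importance samples, DReG for phi.
// E has (B*S*R) x K standard-normal rows, person-major with r fastest.
static double step_core(const mat& Xb, const mat& Mb,
                        const Encoder& enc,
                        const mat& A, const vec& bI,
                        const vec& c_raw, const vec& d_raw, int model,
                        const mat& E, int S, int R, double kl_w, int mode,
                        EncoderGrad& gEnc, DecoderGrad& gDec,
                        int& clamp_count) {
  const int B = Xb.n_rows, J = Xb.n_cols, K = A.n_cols;
  const int SR = S * R, M = B * SR;

  std::vector<mat> Hs;
  mat mu, lv;
  enc_forward(enc, Xb, Hs, mu, lv);
  mat sig = exp(0.5 * lv);

  // constrained asymptotes
  vec cc(J, fill::zeros), dd(J, fill::ones);
  if (model >= 3) cc = 1.0 / (1.0 + exp(-c_raw));
  if (model == 4) dd = 1.0 / (1.0 + exp(-d_raw));

  // replicate persons over samples
  uvec pid(M);
  for (int m = 0; m < M; ++m) pid[m] = m / SR;
  mat Theta = mu.rows(pid) + sig.rows(pid) % E;   // M x K

  mat Z = Theta * A.t();
  Z.each_row() += bI.t();

  // per-person observed item lists: everything likelihood-related is
  // evaluated on observed cells only (masked cells contribute exact zeros)
  std::vector<std::vector<int>> obs(B);
  for (int bi = 0; bi < B; ++bi)
    for (int j = 0; j < J; ++j)
      if (Mb(bi, j) == 1.0) obs[bi].push_back(j);

  vec ll(M, fill::zeros);
  mat G0(M, J, fill::zeros);     // d loglik / d z (zero off-mask)
  mat dLLdP(M, J, fill::zeros);
  mat SG(M, J, fill::zeros);     // sigmoid, observed cells only
  for (int m = 0; m < M; ++m) {
    const int p = pid[m];
    const std::vector<int>& ob = obs[p];
    double acc = 0.0;
    for (size_t t = 0; t < ob.size(); ++t) {
      const int j = ob[t];
      const double s = 1.0 / (1.0 + std::exp(-Z(m, j)));
      double pr = cc[j] + (dd[j] - cc[j]) * s;
      if (pr < P_EPS) pr = P_EPS;
      if (pr > 1.0 - P_EPS) pr = 1.0 - P_EPS;
      const double y = Xb(p, j);
      acc += (y == 1.0) ? std::log(pr) : std::log(1.0 - pr);
      const double dp = (y == 1.0) ? 1.0 / pr : -1.0 / (1.0 - pr);
      SG(m, j) = s;
      dLLdP(m, j) = dp;
      G0(m, j) = dp * s * (1.0 - s) * (dd[j] - cc[j]);
    }
    ll[m] = acc;
  }
  mat dllTheta = G0 * A;                           // d loglik / d theta

  vec u(M, fill::zeros);        // decoder row weights
  mat g_mu(B, K, fill::zeros), g_lv(B, K, fill::zeros);
  double obj = 0.0;

  if (mode == 1) {
    const double w = 1.0 / (double(B) * S);
    u.fill(w);
    obj = w * accu(ll);
    // pathwise encoder gradient of the reconstruction term
    for (int m = 0; m < M; ++m) {
      const int p = pid[m];
      for (int k = 0; k < K; ++k) {
        const double gt = w * dllTheta(m, k);
        g_mu(p, k) += gt;
        g_lv(p, k) += gt * 0.5 * sig(p, k) * E(m, k);
      }
    }
    // analytic KL and its gradient
    mat s2 = exp(lv);
    obj -= kl_w / B * 0.5 * accu(square(mu) + s2 - 1.0 - lv);
    g_mu -= (kl_w / B) * mu;
    g_lv -= (kl_w / B) * 0.5 * (s2 - 1.0);
  } else {
    const double w = 1.0 / (double(B) * S);
    const double logR = std::log((double)R);
    for (int bi = 0; bi < B; ++bi) {
      for (int s = 0; s < S; ++s) {
        int base = (bi * S + s) * R;
        vec v(R);
        double sum_lv = 0.0;
        for (int k = 0; k < K; ++k) sum_lv += lv(bi, k);
        for (int r = 0; r < R; ++r) {
          const int m = base + r;
          double q_theta = 0.0, q_e = 0.0;
          for (int k = 0; k < K; ++k) {
            q_theta += Theta(m, k) * Theta(m, k);
            q_e += E(m, k) * E(m, k);
          }
          // log p - log q; the K/2 log(2 pi) terms cancel
          double vr = ll[m] - 0.5 * q_theta + 0.5 * sum_lv + 0.5 * q_e;
          if (vr > V_CLAMP) { vr = V_CLAMP; ++clamp_count; }
          if (vr < -V_CLAMP) { vr = -V_CLAMP; ++clamp_count; }
          v[r] = vr;
        }
        double vmax = v.max();
        vec ew = exp(v - vmax);
        double sw = accu(ew);
        obj += w * (vmax + std::log(sw) - logR);
        vec wt = ew / sw;                          // normalized weights
        for (int r = 0; r < R; ++r) {
          const int m = base + r;
          u[m] = w * wt[r];
          // DReG: squared weights, pathwise dv/dtheta with q params frozen
          const double w2 = w * wt[r] * wt[r];
          for (int k = 0; k < K; ++k) {
            const double dv = dllTheta(m, k) - Theta(m, k)
                              + E(m, k) / sig(bi, k);
            const double gt = w2 * dv;
            g_mu(bi, k) += gt;
            g_lv(bi, k) += gt * 0.5 * sig(bi, k) * E(m, k);
          }
        }
      }
    }
  }

  // decoder gradients from the weighted rows
  mat Gw = G0.each_col() % u;
  gDec.A += Gw.t() * Theta;
  gDec.b += sum(Gw, 0).t();
  if (model >= 3) {
    mat T = dLLdP % (1.0 - SG);
    T.each_col() %= u;
    gDec.c_raw += sum(T, 0).t() % (cc % (1.0 - cc));
  }
  if (model == 4) {
    mat T = dLLdP % SG;
    T.each_col() %= u;
    gDec.d_raw += sum(T, 0).t() % (dd % (1.0 - dd));
  }

  enc_backward(enc, Hs, g_mu, g_lv, gEnc);
  return obj;
}

// [[Rcpp::export]]
List cpp_objective_grad(const arma::mat& Xb, const arma::mat& Mb, List enc,
                        const arma::mat& A, const arma::vec& b,
                        const arma::vec& c_raw, const arma::vec& d_raw,
                        int model, const arma::mat& E, int S, int R,
                        double kl_weight, int mode) {
  Encoder e = encoder_from_list(enc);
  EncoderGrad gE; gE.zero_like(e);
  DecoderGrad gD;
  gD.A = zeros<mat>(A.n_rows, A.n_cols);
  gD.b = zeros<vec>(b.n_elem);
  gD.c_raw = zeros<vec>(c_raw.n_elem);
  gD.d_raw = zeros<vec>(d_raw.n_elem);
  int clamped = 0;
  double obj = step_core(Xb, Mb, e, A, b, c_raw, d_raw, model,
                         E, S, R, kl_weight, mode, gE, gD, clamped);
  List Ws(gE.W.size()), bs(gE.b.size());
  for (size_t l = 0; l < gE.W.size(); ++l) { Ws[l] = gE.W[l]; bs[l] = gE.b[l]; }
  return List::create(
    _["objective"] = obj,
    _["grad_A"] = gD.A, _["grad_b"] = gD.b,
    _["grad_c_raw"] = gD.c_raw, _["grad_d_raw"] = gD.d_raw,
    _["grad_enc"] = List::create(_["W"] = Ws, _["b"] = bs,
                                 _["W_mu"] = gE.Wmu, _["b_mu"] = gE.bmu,
                                 _["W_lv"] = gE.Wlv, _["b_lv"] = gE.blv),
    _["n_clamped"] = clamped);
}

struct Monitor {
  double best;
  int counter;
  Monitor() : best(-datum::inf), counter(0) {}
  bool update(double wm) {
    if (wm > best) { best = wm; counter = 0; } else { ++counter; }
    return false;
  }
};

// [[Rcpp::export]]
List cpp_fit(const arma::mat& Yfill, const arma::mat& Mask, List enc_init,
             arma::mat A, arma::vec b, arma::vec c_raw, arma::vec d_raw,
             int model, List opts) {
  const int N = Yfill.n_rows, K = A.n_cols;
  const int batch = as<int>(opts["batch_size"]);
  const int S = as<int>(opts["S"]);
  const int R = as<int>(opts["R"]);
  const double lr_main = as<double>(opts["lr_main"]);
  const double lr_asym = as<double>(opts["lr_asymptote"]);
  const int T_max = as<int>(opts["T_max"]);
  const int T_anl = as<int>(opts["T_anl"]);
  const int window = as<int>(opts["window"]);
  const int patience = as<int>(opts["patience"]);
  // stages to run (1 = annealing only); used to test per-stage contracts
  const int n_stages = opts.containsElementNamed("n_stages")
    ? as<int>(opts["n_stages"]) : 3;

  Encoder e = encoder_from_list(enc_init);
  int clamp_total = 0;
  std::vector<std::vector<double>> traces(3);
  std::vector<int> iters(3, 0);
  bool conv2 = false, conv3 = false;

  auto draw_batch = [&](mat& Xb, mat& Mb) {
    uvec idx(batch);
    for (int i = 0; i < batch; ++i) {
      int k = (int)std::floor(R::unif_rand() * N);
      if (k >= N) k = N - 1;
      idx[i] = k;
    }
    Xb = Yfill.rows(idx);
    Mb = Mask.rows(idx);
  };

  auto draw_eps = [&](int rows) {
    mat E(rows, K);
    for (uword i = 0; i < E.n_elem; ++i) E(i) = R::norm_rand();
    return E;
  };

  auto run_stage = [&](int stage) {
    // stage 0: annealed ELBO, fixed length, c/d frozen
    // stage 1: ELBO until windowed convergence; stage 2: IW-ELBO + DReG
    int mode = (stage == 2) ? 2 : 1;
    int Ruse = (stage == 2) ? R : 1;
    Monitor mon;
    double wsum = 0.0;
    int t = 0;
    const int tmax = (stage == 0) ? T_anl : T_max;
    while (t < tmax) {
      ++t;
      if (t % 1024 == 0) Rcpp::checkUserInterrupt();
      mat Xb, Mb;
      draw_batch(Xb, Mb);
      mat E = draw_eps(batch * S * Ruse);
      double kl_w = (stage == 0) ? std::min(1.0, double(t) / T_anl) : 1.0;
      EncoderGrad gE; gE.zero_like(e);
      DecoderGrad gD;
      gD.A = zeros<mat>(A.n_rows, A.n_cols);
      gD.b = zeros<vec>(b.n_elem);
      gD.c_raw = zeros<vec>(c_raw.n_elem);
      gD.d_raw = zeros<vec>(d_raw.n_elem);
      double obj = step_core(Xb, Mb, e, A, b, c_raw, d_raw, model,
                             E, S, Ruse, kl_w, mode, gE, gD, clamp_total);
      if (!std::isfinite(obj)) stop("non-finite objective at step %d of stage %d", t, stage + 1);
      // gradient ascent, fixed step sizes
      for (size_t l = 0; l < e.W.size(); ++l) {
        e.W[l] += lr_main * gE.W[l];
        e.b[l] += lr_main * gE.b[l];
      }
      e.Wmu += lr_main * gE.Wmu;  e.bmu += lr_main * gE.bmu;
      e.Wlv += lr_main * gE.Wlv;  e.blv += lr_main * gE.blv;
      A += lr_main * gD.A;
      b += lr_main * gD.b;
      if (stage > 0) {           // c, d frozen during annealing
        if (model >= 3) c_raw += lr_asym * gD.c_raw;
        if (model == 4) d_raw += lr_asym * gD.d_raw;
      }
      wsum += obj;
      if (t % window == 0) {
        double wm = wsum / window;
        wsum = 0.0;
        traces[stage].push_back(wm);
        if (stage > 0) {
          mon.update(wm);
          if (mon.counter >= patience) { iters[stage] = t; return true; }
        }
      }
    }
    iters[stage] = t;
    return stage == 0;           // annealing stage always "succeeds"
  };

  bool ok1 = run_stage(0);
  conv2 = (n_stages >= 2) ? run_stage(1) : true;
  conv3 = (n_stages >= 3) ? run_stage(2) : true;
  (void)ok1;

  return List::create(
    _["A"] = A, _["b"] = b, _["c_raw"] = c_raw, _["d_raw"] = d_raw,
    _["encoder"] = encoder_to_list(e),
    _["trace_anneal"] = traces[0],
    _["trace_elbo"] = traces[1],
    _["trace_iwelbo"] = traces[2],
    _["iterations"] = IntegerVector::create(iters[0], iters[1], iters[2]),
    _["converged"] = LogicalVector::create(true, conv2, conv3),
    _["n_clamped"] = clamp_total);
}
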