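// Compiled core: LSTM forward pass, truncated backpropagation-through-time
// for the actor-critic objective, Adam updates, and the episode rollout
// loops used for training and evaluation.
//
// Action index convention (matches the input-vector layout used throughout
// the package): 0 = "yes"/match, 1 = "no"/no-match.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const int N_PAR = 16;
static const char* PAR_NAMES[N_PAR] = {
  "Wxf", "Whf", "Wxi", "Whi", "Wxo", "Who", "Wxc", "Whc",
  "bf",  "bi",  "bo",  "bc",  "Wp",  "bp",  "Wv",  "bv"};

enum ParIdx { iWxf, iWhf, iWxi, iWhi, iWxo, iWho, iWxc, iWhc,
              ibf, ibi, ibo, ibc, iWp, ibp, iWv, ibv };

struct Net {
  std::vector<mat> P;
  int n, d;

  explicit Net(const List& params) {
    P.reserve(N_PAR);
    for (int k = 0; k < N_PAR; ++k)
      P.push_back(as<mat>(params[PAR_NAMES[k]]));
    n = P[iWhf].n_rows;
    d = P[iWxf].n_cols;
  }

  List to_list() const {
    List out(N_PAR);
    CharacterVector nm(N_PAR);
    for (int k = 0; k < N_PAR; ++k) {
      out[k] = wrap(P[k]);
      nm[k] = PAR_NAMES[k];
    }
    out.attr("names") = nm;
    return out;
  }
};

static inline vec sigm(const vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// Per-timestep forward cache needed by the backward pass.
struct Cache {
  vec x, hprev, cprev, f, i, o, g, c, h, logits, pi;
  double V;
  int a;       // sampled/required action (0 = yes, 1 = no)
  double r;    // reward received at this timestep
  bool dec;    // decision timestep?
};

// One LSTM step + linear policy/value heads. h and c are updated in place.
static void step_net(const Net& net, const vec& x, vec& h, vec& c, Cache& cc) {
  cc.x = x;
  cc.hprev = h;
  cc.cprev = c;
  cc.f = sigm(net.P[iWxf] * x + net.P[iWhf] * h + net.P[ibf]);
  cc.i = sigm(net.P[iWxi] * x + net.P[iWhi] * h + net.P[ibi]);
  cc.o = sigm(net.P[iWxo] * x + net.P[iWho] * h + net.P[ibo]);
  cc.g = arma::tanh(net.P[iWxc] * x + net.P[iWhc] * h + net.P[ibc]);
  cc.c = cc.f % c + cc.i % cc.g;
  cc.h = cc.o % arma::tanh(cc.c);
  cc.logits = net.P[iWp] * cc.h + net.P[ibp];
  double mx = cc.logits.max();
  vec e = arma::exp(cc.logits - mx);
  cc.pi = e / arma::accu(e);
  cc.V = arma::as_scalar(net.P[iWv] * cc.h) + net.P[ibv](0, 0);
  h = cc.h;
  c = cc.c;
}

// Backward pass over a segment of cached timesteps. Accumulates parameter
// gradients of
//   L = sum_t [ -log pi(a_t) * delta_t  +  beta_v * delta_t^2
//               - beta_H * H(pi_t) ]
// with delta_t = R_t - V_t treated as a constant in the policy term and
// R_t the discounted return (bootstrapped with 0 past the segment end,
// exact for gamma = 0). Returns loss components through `comp`.
static void backward_segment(const Net& net, std::vector<Cache>& seg,
                             double gamma, double beta_v, double beta_h,
                             bool decision_only,
                             std::vector<mat>& G, double comp[4]) {
  const int T = (int)seg.size();
  const int n = net.n;
  std::vector<double> R(T), delta(T);
  double run = 0.0;
  for (int t = T - 1; t >= 0; --t) {
    run = seg[t].r + gamma * run;
    R[t] = run;
  }
  double Lpol = 0, Lval = 0, Hsum = 0;
  for (int t = 0; t < T; ++t) delta[t] = R[t] - seg[t].V;

  vec dh_next(n, arma::fill::zeros), dc_next(n, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const Cache& cc = seg[t];
    vec dh = dh_next;
    bool scored = !decision_only || cc.dec;
    if (scored) {
      vec logpi = arma::log(cc.pi);
      double H = -arma::accu(cc.pi % logpi);
      Lpol += -logpi(cc.a) * delta[t];
      Lval += beta_v * delta[t] * delta[t];
      Hsum += H;

      // heads
      vec dlogit(2);
      for (int j = 0; j < 2; ++j) {
        dlogit(j) = delta[t] * (cc.pi(j) - (j == cc.a ? 1.0 : 0.0))
                  + beta_h * cc.pi(j) * (logpi(j) + H);
      }
      double dV = -2.0 * beta_v * delta[t];
      G[iWp] += dlogit * cc.h.t();
      G[ibp] += dlogit;
      G[iWv] += dV * cc.h.t();
      G[ibv](0, 0) += dV;
      dh += net.P[iWp].t() * dlogit + net.P[iWv].t() * dV;
    }

    // LSTM backward
    vec tc = arma::tanh(cc.c);
    vec do_ = dh % tc;
    vec dc = dc_next + dh % cc.o % (1.0 - tc % tc);
    vec df = dc % cc.cprev;
    vec di = dc % cc.g;
    vec dg = dc % cc.i;
    dc_next = dc % cc.f;
    vec daf = df % cc.f % (1.0 - cc.f);
    vec dai = di % cc.i % (1.0 - cc.i);
    vec dao = do_ % cc.o % (1.0 - cc.o);
    vec dag = dg % (1.0 - cc.g % cc.g);

    G[iWxf] += daf * cc.x.t();  G[iWhf] += daf * cc.hprev.t();  G[ibf] += daf;
    G[iWxi] += dai * cc.x.t();  G[iWhi] += dai * cc.hprev.t();  G[ibi] += dai;
    G[iWxo] += dao * cc.x.t();  G[iWho] += dao * cc.hprev.t();  G[ibo] += dao;
    G[iWxc] += dag * cc.x.t();  G[iWhc] += dag * cc.hprev.t();  G[ibc] += dag;

    dh_next = net.P[iWhf].t() * daf + net.P[iWhi].t() * dai
            + net.P[iWho].t() * dao + net.P[iWhc].t() * dag;
  }
  comp[0] = Lpol + Lval - beta_h * Hsum;
  comp[1] = Lpol;
  comp[2] = Lval;
  comp[3] = Hsum;
}

struct TaskCfg {
  bool one_hot;
  int set_size, enc_len, trial_size, d;
  bool recency;
  double r_correct, r_incorrect, r_xaxa, r_xxaa;
  double gamma, lr, beta_v, beta_h;
  int update_every;
  bool decision_only;

  explicit TaskCfg(const List& cfg, int trial_size_) {
    std::string enc = as<std::string>(cfg["encoding"]);
    one_hot = (enc == "one_hot");
    set_size = as<int>(cfg["set_size"]);
    enc_len = one_hot ? set_size : 1;
    trial_size = trial_size_;
    d = enc_len + 3;
    recency = as<bool>(cfg["recency"]);
    r_correct = as<double>(cfg["reward_correct"]);
    r_incorrect = as<double>(cfg["reward_incorrect"]);
    r_xaxa = as<double>(cfg["reward_xaxa"]);
    r_xxaa = as<double>(cfg["reward_xxaa"]);
    gamma = as<double>(cfg["gamma"]);
    lr = as<double>(cfg["lr"]);
    beta_v = as<double>(cfg["beta_v"]);
    beta_h = as<double>(cfg["beta_h"]);
    update_every = as<int>(cfg["update_every"]);
    decision_only = as<bool>(cfg["decision_only"]);
  }
};

// Input vector: [cue encoding, one-hot previous action (yes, no), prev reward].
static void fill_input(vec& x, const TaskCfg& tc, int cue, int prev_a,
                       double prev_r) {
  x.zeros();
  if (cue > 0) {
    if (tc.one_hot) x(cue - 1) = 1.0; else x(0) = (double)cue;
  }
  if (prev_a >= 0) x(tc.enc_len + prev_a) = 1.0;
  x(tc.enc_len + 2) = prev_r;
}

// Recency position of the test cue: largest j < K with cue_j == cue_K,
// reported as j - K (e.g. -1, -2, ...); 0 if no prior occurrence.
static int recency_pos(const IntegerMatrix& trials, int ep) {
  int K = trials.ncol();
  int test = trials(ep, K - 1);
  for (int j = K - 2; j >= 0; --j)
    if (trials(ep, j) == test) return j + 1 - K;
  return 0;
}

static double decision_reward(const TaskCfg& tc, const IntegerMatrix& trials,
                              int ep, bool is_match, int a, bool& correct) {
  bool yes = (a == 0);
  correct = (is_match == yes);
  if (correct) return tc.r_correct;
  if (tc.recency && yes && !is_match) {
    int pos = recency_pos(trials, ep);
    if (pos == -2) return tc.r_xaxa;
    if (pos == -1) return tc.r_xxaa;
  }
  return tc.r_incorrect;
}

// [[Rcpp::export]]
List cpp_train(List params, IntegerMatrix trials, IntegerVector labels,
               List cfg, IntegerVector checkpoints) {
  Net net(params);
  TaskCfg tc(cfg, trials.ncol());
  if (net.d != tc.d) stop("agent input dimension does not match task encoding");
  const int n_ep = trials.nrow();

  // Adam state
  std::vector<mat> G(N_PAR), m(N_PAR), v(N_PAR);
  for (int k = 0; k < N_PAR; ++k) {
    G[k] = arma::zeros<mat>(net.P[k].n_rows, net.P[k].n_cols);
    m[k] = G[k];
    v[k] = G[k];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long adam_t = 0;

  vec h(net.n, arma::fill::zeros), c(net.n, arma::fill::zeros);
  vec x(net.d);
  int prev_a = -1;
  double prev_r = 0.0;
  std::vector<Cache> seg;
  seg.reserve((size_t)tc.update_every * (tc.trial_size + 1));
  int trials_in_seg = 0;

  std::vector<int> cps = as<std::vector<int>>(checkpoints);
  std::sort(cps.begin(), cps.end());
  List cp_out(cps.size());
  CharacterVector cp_names(cps.size());
  size_t cp_i = 0;
  while (cp_i < cps.size() && cps[cp_i] <= 0) {
    cp_out[cp_i] = net.to_list();
    cp_names[cp_i] = std::to_string(cps[cp_i]);
    ++cp_i;
  }

  IntegerVector correct_log(n_ep);
  double comp[4];

  for (int ep = 0; ep < n_ep; ++ep) {
    bool is_match = (labels[ep] == 1);
    for (int pos = 0; pos <= tc.trial_size; ++pos) {
      int cue = (pos == 0) ? 0 : trials(ep, pos - 1);
      fill_input(x, tc, cue, prev_a, prev_r);
      Cache cc;
      step_net(net, x, h, c, cc);
      double u = R::unif_rand();
      cc.a = (u < cc.pi(0)) ? 0 : 1;
      cc.dec = (pos == tc.trial_size);
      cc.r = 0.0;
      if (cc.dec) {
        bool correct;
        cc.r = decision_reward(tc, trials, ep, is_match, cc.a, correct);
        correct_log[ep] = correct ? 1 : 0;
      }
      prev_a = cc.a;
      prev_r = cc.r;
      seg.push_back(std::move(cc));
    }
    if (++trials_in_seg == tc.update_every) {
      for (int k = 0; k < N_PAR; ++k) G[k].zeros();
      backward_segment(net, seg, tc.gamma, tc.beta_v, tc.beta_h,
                       tc.decision_only, G, comp);
      if (!std::isfinite(comp[0]))
        stop("training diverged: non-finite loss at episode %d", ep + 1);
      ++adam_t;
      double bc1 = 1.0 - std::pow(b1, (double)adam_t);
      double bc2 = 1.0 - std::pow(b2, (double)adam_t);
      for (int k = 0; k < N_PAR; ++k) {
        m[k] = b1 * m[k] + (1.0 - b1) * G[k];
        v[k] = b2 * v[k] + (1.0 - b2) * (G[k] % G[k]);
        net.P[k] -= tc.lr * (m[k] / bc1) / (arma::sqrt(v[k] / bc2) + eps);
      }
      seg.clear();
      trials_in_seg = 0;
    }
    while (cp_i < cps.size() && cps[cp_i] == ep + 1) {
      cp_out[cp_i] = net.to_list();
      cp_names[cp_i] = std::to_string(cps[cp_i]);
      ++cp_i;
    }
  }
  while (cp_i < cps.size()) {
    cp_out[cp_i] = net.to_list();
    cp_names[cp_i] = std::to_string(cps[cp_i]);
    ++cp_i;
  }
  cp_out.attr("names") = cp_names;
  return List::create(_["checkpoints"] = cp_out,
                      _["correct"] = correct_log);
}

// [[Rcpp::export]]
List cpp_evaluate(List params, IntegerMatrix trials, IntegerVector labels,
                  List cfg, bool record_states, bool record_steps) {
  Net net(params);
  TaskCfg tc(cfg, trials.ncol());
  if (net.d != tc.d) stop("agent input dimension does not match task encoding");
  const int n_ep = trials.nrow();
  const int K = tc.trial_size;

  vec h(net.n, arma::fill::zeros), c(net.n, arma::fill::zeros);
  vec x(net.d);
  int prev_a = -1;
  double prev_r = 0.0;

  LogicalVector resp_yes(n_ep), correct(n_ep);
  NumericVector reward(n_ep), pi_yes(n_ep), value_dec(n_ep);
  arma::cube states;
  if (record_states) states.zeros(n_ep, K, net.n);

  int n_steps = record_steps ? n_ep * (K + 1) : 0;
  IntegerVector st_t(n_steps), st_trial(n_steps), st_cue(n_steps),
      st_action(n_steps);
  LogicalVector st_dec(n_steps);
  NumericVector st_r(n_steps), st_pi(n_steps), st_V(n_steps);

  Cache cc;
  int t_global = 0;
  for (int ep = 0; ep < n_ep; ++ep) {
    bool is_match = (labels[ep] == 1);
    for (int pos = 0; pos <= K; ++pos) {
      int cue = (pos == 0) ? 0 : trials(ep, pos - 1);
      fill_input(x, tc, cue, prev_a, prev_r);
      step_net(net, x, h, c, cc);
      double u = R::unif_rand();
      int a = (u < cc.pi(0)) ? 0 : 1;
      double r = 0.0;
      bool dec = (pos == K);
      if (dec) {
        bool ok;
        r = decision_reward(tc, trials, ep, is_match, a, ok);
        resp_yes[ep] = (a == 0);
        correct[ep] = ok;
        reward[ep] = r;
        pi_yes[ep] = cc.pi(0);
        value_dec[ep] = cc.V;
      }
      if (record_states && pos >= 1)
        for (int q = 0; q < net.n; ++q) states(ep, pos - 1, q) = h(q);
      if (record_steps) {
        st_t[t_global] = t_global + 1;
        st_trial[t_global] = ep + 1;
        st_cue[t_global] = cue;
        st_dec[t_global] = dec;
        st_action[t_global] = a;
        st_r[t_global] = r;
        st_pi[t_global] = cc.pi(0);
        st_V[t_global] = cc.V;
      }
      prev_a = a;
      prev_r = r;
      ++t_global;
    }
  }
  List out = List::create(
      _["response_yes"] = resp_yes, _["correct"] = correct,
      _["reward"] = reward, _["pi_yes"] = pi_yes, _["value"] = value_dec);
  if (record_states) out["states"] = wrap(states);
  if (record_steps)
    out["steps"] = DataFrame::create(
        _["t"] = st_t, _["trial"] = st_trial, _["cue"] = st_cue,
        _["is_decision"] = st_dec, _["action_yes"] = st_action,
        _["reward"] = st_r, _["pi_yes"] = st_pi, _["value"] = st_V);
  return out;
}

// [[Rcpp::export]]
List cpp_lstm_forward(List params, NumericMatrix X, NumericVector h0,
                      NumericVector c0) {
  Net net(params);
  const int T = X.nrow();
  if (X.ncol() != net.d) stop("input matrix has wrong dimension");
  vec h = as<vec>(h0), c = as<vec>(c0);
  mat H(T, net.n), C(T, net.n), PI(T, 2);
  NumericVector V(T);
  Cache cc;
  vec x(net.d);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < net.d; ++j) x(j) = X(t, j);
    step_net(net, x, h, c, cc);
    H.row(t) = h.t();
    C.row(t) = c.t();
    PI.row(t) = cc.pi.t();
    V[t] = cc.V;
  }
  return List::create(_["h"] = H, _["c"] = C, _["pi"] = PI, _["value"] = V);
}

// [[Rcpp::export]]
List cpp_segment_grad(List params, NumericMatrix X, IntegerVector actions,
                      NumericVector rewards, LogicalVector is_decision,
                      double gamma, double beta_v, double beta_h,
                      bool decision_only, NumericVector h0,
                      NumericVector c0) {
  Net net(params);
  const int T = X.nrow();
  if (X.ncol() != net.d) stop("input matrix has wrong dimension");
  vec h = as<vec>(h0), c = as<vec>(c0);
  std::vector<Cache> seg(T);
  vec x(net.d);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < net.d; ++j) x(j) = X(t, j);
    step_net(net, x, h, c, seg[t]);
    seg[t].a = actions[t];
    seg[t].r = rewards[t];
    seg[t].dec = is_decision[t];
  }
  std::vector<mat> G(N_PAR);
  for (int k = 0; k < N_PAR; ++k)
    G[k] = arma::zeros<mat>(net.P[k].n_rows, net.P[k].n_cols);
  double comp[4];
  backward_segment(net, seg, gamma, beta_v, beta_h, decision_only, G, comp);
  List gl(N_PAR);
  CharacterVector nm(N_PAR);
  for (int k = 0; k < N_PAR; ++k) {
    gl[k] = wrap(G[k]);
    nm[k] = PAR_NAMES[k];
  }
  gl.attr("names") = nm;
  NumericVector adv(T), val(T);
  {
    double run = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      run = rewards[t] + gamma * run;
      adv[t] = run - seg[t].V;
      val[t] = seg[t].V;
    }
  }
  return List::create(_["loss"] = comp[0], _["policy_loss"] = comp[1],
                      _["value_loss"] = comp[2], _["entropy"] = comp[3],
                      _["advantage"] = adv, _["value"] = val,
                      _["grads"] = gl);
}
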