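// Core simulation engine: k-winners-take-all settling dynamics,
// two-phase contrastive weight updates, and the per-trial loop with
// TD critic and maintenance-gate updates.  All stochastic draws are
// made in R and passed in as data; this file is fully deterministic.
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;

struct Params {
  int k_hid, k_pfc, k_resp, max_cycles;
  double gain, bias, dt, dt_pfc, tol, a_on, wmin, wmax, noise_decay;
  bool resp_pooled;
  int n_features;
};

static Params read_params(const List& cfg) {
  Params p;
  p.k_hid = as<int>(cfg["k_hidden"]);
  p.k_pfc = as<int>(cfg["k_pfc"]);
  p.k_resp = as<int>(cfg["k_response"]);
  p.max_cycles = as<int>(cfg["max_cycles"]);
  p.gain = as<double>(cfg["gain"]);
  p.bias = as<double>(cfg["bias"]);
  p.dt = as<double>(cfg["dt"]);
  p.dt_pfc = as<double>(cfg["dt_pfc"]);
  p.tol = as<double>(cfg["tol"]);
  p.a_on = as<double>(cfg["a_on"]);
  p.wmin = as<double>(cfg["w_min"]);
  p.wmax = as<double>(cfg["w_max"]);
  p.noise_decay = as<double>(cfg["noise_decay"]);
  p.resp_pooled = as<bool>(cfg["resp_pooled"]);
  p.n_features = as<int>(cfg["n_features"]);
  return p;
}

// Weight matrices, target x source, with fixed relative projection scales
// (the analog of per-projection net-input scaling in rate-coded frameworks).
struct Net {
  mat i1h, i2h, th, ph, rh;  // -> hidden (rh: response feedback)
  mat hr, pr, rr, ir1, ir2;  // -> response (rr: fixed lateral)
  mat hp, tp, cp, pp;        // -> pfc
  double s_i1h, s_i2h, s_th, s_ph, s_rh, s_hr, s_pr, s_rr, s_ir, s_hp, s_tp,
         s_cp, s_pp;
};

static Net read_net(const List& w, const List& cfg) {
  Net N;
  N.i1h = as<mat>(w["in1_hid"]);
  N.i2h = as<mat>(w["in2_hid"]);
  N.th  = as<mat>(w["task_hid"]);
  N.ph  = as<mat>(w["pfc_hid"]);
  N.hr  = as<mat>(w["hid_resp"]);
  N.pr  = as<mat>(w["pfc_resp"]);
  N.rr  = as<mat>(w["resp_resp"]);
  N.hp  = as<mat>(w["hid_pfc"]);
  N.tp  = as<mat>(w["task_pfc"]);
  N.cp  = as<mat>(w["cue_pfc"]);
  N.pp  = as<mat>(w["pfc_pfc"]);
  N.rh  = as<mat>(w["resp_hid"]);
  N.ir1 = as<mat>(w["in1_resp"]);
  N.ir2 = as<mat>(w["in2_resp"]);
  N.s_i1h = as<double>(cfg["sc_in_hid"]);
  N.s_i2h = N.s_i1h;
  N.s_th  = as<double>(cfg["sc_task_hid"]);
  N.s_ph  = as<double>(cfg["sc_pfc_hid"]);
  N.s_rh  = as<double>(cfg["sc_resp_hid"]);
  N.s_hr  = as<double>(cfg["sc_hid_resp"]);
  N.s_pr  = as<double>(cfg["sc_pfc_resp"]);
  N.s_rr  = 1.0;
  N.s_ir  = as<double>(cfg["sc_in_resp"]);
  N.s_hp  = as<double>(cfg["sc_hid_pfc"]);
  N.s_tp  = as<double>(cfg["sc_task_pfc"]);
  N.s_cp  = as<double>(cfg["sc_cue_pfc"]);
  N.s_pp  = as<double>(cfg["sc_pfc_pfc"]);
  return N;
}

static inline double sig(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Average-free kWTA: a shared inhibition level is placed between the k-th
// and (k+1)-th largest net inputs (stable order; ties broken by lowest
// index).  An exact tie at the winner/loser boundary with positive drive is
// resolved by granting winners a fixed positive margin and losers the
// mirrored negative margin.  Ties at or below zero drive fall back to the
// zero inhibition floor (the resting state stays quiescent).
static void kwta(const vec& net, int k, double gain, double bias, vec& out) {
  const int n = net.n_elem;
  out.set_size(n);
  if (k >= n) {  // inhibition at floor: no competition
    for (int i = 0; i < n; ++i) out(i) = sig(gain * (net(i) - bias));
    return;
  }
  arma::uvec ord = arma::stable_sort_index(net, "descend");
  const double nk = net(ord(k - 1)), nk1 = net(ord(k));
  if (nk > nk1) {
    const double thr = 0.5 * (nk + nk1);
    for (int i = 0; i < n; ++i) out(i) = sig(gain * (net(i) - thr - bias));
  } else if (nk > 0.0) {
    const double tm = bias + 2.0 / gain;  // winner activation = sig(2) > a_on
    std::vector<char> win(n, 0);
    for (int i = 0; i < k; ++i) win[ord(i)] = 1;
    const double thrW = nk - tm, thrL = nk1 + tm;
    for (int i = 0; i < n; ++i)
      out(i) = sig(gain * (net(i) - (win[i] ? thrW : thrL) - bias));
  } else {
    for (int i = 0; i < n; ++i) out(i) = sig(gain * (net(i) - bias));
  }
}

static void kwta_resp_pooled(const vec& net, int nf, double gain,
                             double bias, vec& out);

// Iterate activation updates until the largest elementwise change drops
// below tol, or max_cycles is reached.  Returns the cycle count (the
// settling-time readout).  `warm` keeps the caller-provided activations as
// the starting state (used for the outcome phase of learning).
static int settle_core(const Net& W, const Params& P,
                       const vec& in1, const vec& in2,
                       const vec& task, const vec& cue,
                       const vec& maint, const vec& pnoise,
                       const vec* rnoise, const vec* clamp,
                       vec& hid, vec& pfc, vec& resp,
                       bool warm, bool& conv, int* label_cycles = nullptr) {
  const int nh = W.i1h.n_rows, np = W.pp.n_rows, nr = W.hr.n_rows;
  const double b0 = sig(-P.gain * P.bias);  // resting activation
  if (!warm) {
    hid.set_size(nh);  hid.fill(b0);
    pfc.set_size(np);  pfc.fill(b0);
    resp.set_size(nr); resp.fill(b0);
  }
  conv = false;
  vec th(nh), tp(np), tr(nr);
  vec pn = pnoise;  // transient: decays over settling cycles
  // label (feature-column) activity: its stabilisation time is the
  // vocal-response settling readout
  const int nf = P.n_features;
  vec lab(nf, arma::fill::zeros), labprev(nf, arma::fill::zeros);
  int lab_last = 1;
  for (int c = 1; c <= P.max_cycles; ++c) {
    vec neth = W.s_i1h * (W.i1h * in1) + W.s_i2h * (W.i2h * in2) +
               W.s_th * (W.th * task) + W.s_ph * (W.ph * pfc) +
               W.s_rh * (W.rh * resp);
    vec netp = W.s_hp * (W.hp * hid) + W.s_tp * (W.tp * task) +
               W.s_cp * (W.cp * cue) + W.s_pp * (W.pp * pfc) + maint + pn;
    pn *= P.noise_decay;
    vec netr = W.s_hr * (W.hr * hid) + W.s_pr * (W.pr * pfc) +
               W.s_rr * (W.rr * resp) +
               W.s_ir * (W.ir1 * in1 + W.ir2 * in2);
    if (rnoise) netr += *rnoise;
    kwta(neth, P.k_hid, P.gain, P.bias, th);
    kwta(netp, P.k_pfc, P.gain, P.bias, tp);
    if (P.resp_pooled) kwta_resp_pooled(netr, P.n_features, P.gain, P.bias, tr);
    else kwta(netr, P.k_resp, P.gain, P.bias, tr);
    vec nhid = hid + P.dt * (th - hid);
    vec npfc = pfc + P.dt_pfc * (tp - pfc);
    vec nresp = clamp ? *clamp : resp + P.dt * (tr - resp);
    double d = std::max(arma::abs(nhid - hid).max(),
                        std::max(arma::abs(npfc - pfc).max(),
                                 arma::abs(nresp - resp).max()));
    hid = nhid; pfc = npfc; resp = nresp;
    if (label_cycles) {
      lab.fill(-arma::datum::inf);
      for (int i = 0; i < nr; ++i)
        lab(i % nf) = std::max(lab(i % nf), resp(i));
      if (c == 1 || arma::abs(lab - labprev).max() >= P.tol) lab_last = c;
      labprev = lab;
    }
    if (d < P.tol) {
      conv = true;
      if (label_cycles) *label_cycles = lab_last;
      return c;
    }
  }
  if (label_cycles) *label_cycles = lab_last;
  return P.max_cycles;
}

// Grouped response inhibition: units sharing a feature column (verbal
// label) pool their net input; columns compete winner-take-all, then the
// winning column's units compete internally.  Models a shared vocal
// response across stimulus dimensions.
static void kwta_resp_pooled(const vec& net, int nf, double gain, double bias,
                             vec& out) {
  const int n = net.n_elem;
  const int nd = n / nf;
  out.set_size(n);
  // column score: the strongest member carries the label coalition
  vec colnet(nf, arma::fill::value(-arma::datum::inf));
  for (int i = 0; i < n; ++i) colnet(i % nf) = std::max(colnet(i % nf), net(i));
  arma::uvec ord = arma::stable_sort_index(colnet, "descend");
  const int cw = ord(0);
  const double tm = bias + 2.0 / gain;
  if (colnet(cw) <= 0.0) {  // nothing driven: inhibition floor, no race
    for (int i = 0; i < n; ++i) out(i) = sig(gain * (net(i) - bias));
    return;
  }
  // the label race sets the expressed unit's drive: its threshold is the
  // midpoint between the winning and runner-up coalition scores
  double thrW;
  if (nf > 1 && colnet(cw) > colnet(ord(1)))
    thrW = 0.5 * (colnet(cw) + colnet(ord(1)));
  else if (colnet(cw) > 0)
    thrW = colnet(cw) - tm;
  else
    thrW = 0.0;
  // best member of the winning column expresses the label
  int best = -1; double bestnet = -arma::datum::inf;
  for (int d = 0; d < nd; ++d) {
    double v = net(d * nf + cw);
    if (v > bestnet) { bestnet = v; best = d * nf + cw; }
  }
  for (int i = 0; i < n; ++i) {
    double thr = (i == best) ? thrW : net(i) + tm;
    out(i) = sig(gain * (net(i) - thr - bias));
  }
}

static int read_resp(const vec& resp, double a_on) {
  arma::uword idx;
  double m = resp.max(idx);
  return (m > a_on) ? static_cast<int>(idx) : -1;
}

// Contrastive two-phase update: weights move with the difference of
// outcome-phase and expectation-phase co-activation products.
static void chl(mat& W, const vec& tp, const vec& sp,
                const vec& tm, const vec& sm, double lr, const Params& P) {
  mat d = tp * sp.t() - tm * sm.t();
  // soft bounding: potentiation scales with headroom, depression with the
  // distance to the floor, keeping weights interior and learning stable
  W += lr * (arma::clamp(d, 0.0, arma::datum::inf) % (P.wmax - W) +
             arma::clamp(d, -arma::datum::inf, 0.0) % (W - P.wmin));
  W = arma::clamp(W, P.wmin, P.wmax);
}

// [[Rcpp::export]]
NumericVector cpp_kwta(const arma::vec& net, int k, double gain, double bias) {
  vec out;
  kwta(net, k, gain, bias, out);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_settle(List weights, List cfg,
                const arma::vec& in1, const arma::vec& in2,
                const arma::vec& task, const arma::vec& cue,
                const arma::vec& maint, const arma::vec& pnoise,
                Nullable<NumericVector> resp_clamp,
                Nullable<NumericVector> resp_noise = R_NilValue) {
  Params P = read_params(cfg);
  Net W = read_net(weights, cfg);
  vec hid, pfc, resp;
  bool conv = false;
  const vec* cl = nullptr;
  vec clv;
  if (resp_clamp.isNotNull()) {
    clv = as<vec>(resp_clamp.get());
    cl = &clv;
  }
  const vec* rn = nullptr;
  vec rnv;
  if (resp_noise.isNotNull()) {
    rnv = as<vec>(resp_noise.get());
    rn = &rnv;
  }
  int labc = 0;
  int cyc = settle_core(W, P, in1, in2, task, cue, maint, pnoise, rn, cl,
                        hid, pfc, resp, false, conv, &labc);
  return List::create(_["hidden"] = wrap(hid), _["pfc"] = wrap(pfc),
                      _["response"] = wrap(resp), _["cycles"] = cyc,
                      _["label_cycles"] = labc,
                      _["converged"] = conv);
}

// Run a block of trials.  Each row of in1m/in2m is a clamped input pattern;
// task/cue are 0-based unit indices (-1 = off); target is the 0-based
// response unit carrying the corrective-feedback pattern.  noise holds one
// pre-drawn standard-normal row per trial for destabilisation.
// [[Rcpp::export]]
List cpp_run_trials(List weights, List cfg,
                    const arma::mat& in1m, const arma::mat& in2m,
                    const IntegerVector& task, const IntegerVector& cue,
                    const IntegerVector& target,
                    const arma::vec& maint_in, const arma::vec& critic_in,
                    const arma::vec& pnoise_in,
                    double kappa, double alpha, double maintenance_gain,
                    double noise_sd, double gate_floor, double gate_power,
                    double delta_tol, double lrate,
                    const arma::mat& noise,
                    bool do_learn, bool do_gate) {
  Params P = read_params(cfg);
  Net W = read_net(weights, cfg);
  const double lr_pfc_out = as<double>(cfg["lr_pfc_mult"]);
  const double lr_direct = as<double>(cfg["lr_direct_mult"]);
  const int kick_width = as<int>(cfg["kick_width"]);
  const int n = in1m.n_rows;
  const int ntask = W.th.n_cols, ncue = W.cp.n_cols;
  const int nresp = W.hr.n_rows, npfc = W.pp.n_rows;
  vec maint = maint_in, critic = critic_in, pnoise = pnoise_in;
  IntegerVector resp_out(n), cyc_out(n), act_out(n), lab_out(n);
  LogicalVector corr_out(n), conv_out(n);
  NumericVector delta_out(n);
  vec hid, pfc, resp, hid2, pfc2, resp2;
  for (int i = 0; i < n; ++i) {
    vec v1 = in1m.row(i).t(), v2 = in2m.row(i).t();
    vec tv(ntask, arma::fill::zeros);
    if (task[i] >= 0) tv(task[i]) = 1.0;
    vec cv(ncue, arma::fill::zeros);
    if (cue[i] >= 0) cv(cue[i]) = 1.0;
    bool conv = false;
    int labc = 0;
    int cyc = settle_core(W, P, v1, v2, tv, cv, maint, pnoise, nullptr,
                          nullptr, hid, pfc, resp, false, conv, &labc);
    int r = read_resp(resp, P.a_on);
    bool correct = (r >= 0 && r == target[i]);
    resp_out[i] = r; cyc_out[i] = cyc; lab_out[i] = labc;
    corr_out[i] = correct; conv_out[i] = conv;
    if (do_learn && target[i] >= 0) {
      vec clampv(nresp, arma::fill::zeros);
      clampv(target[i]) = 1.0;
      hid2 = hid; pfc2 = pfc; resp2 = resp;
      bool conv2 = false;
      settle_core(W, P, v1, v2, tv, cv, maint, pnoise, nullptr, &clampv,
                  hid2, pfc2, resp2, true, conv2);
      chl(W.i1h, hid2, v1, hid, v1, lrate, P);
      chl(W.i2h, hid2, v2, hid, v2, lrate, P);
      chl(W.th,  hid2, tv, hid, tv, lrate, P);
      chl(W.ph,  hid2, pfc2, hid, pfc, lrate, P);
      chl(W.hr,  resp2, hid2, resp, hid, lrate, P);
      chl(W.pr,  resp2, pfc2, resp, pfc, lrate * lr_pfc_out, P);
      chl(W.hp,  pfc2, hid2, pfc, hid, lrate, P);
      chl(W.tp,  pfc2, tv, pfc, tv, lrate, P);
      chl(W.cp,  pfc2, cv, pfc, cv, lrate, P);
      chl(W.pp,  pfc2, pfc2, pfc, pfc, lrate * lr_pfc_out, P);
      chl(W.rh,  hid2, resp2, hid, resp, lrate, P);
      chl(W.ir1, resp2, v1, resp, v1, lrate * lr_direct, P);
      chl(W.ir2, resp2, v2, resp, v2, lrate * lr_direct, P);
    }
    // pending destabilisation noise applies to this trial's settle only
    pnoise.zeros(npfc);
    double dlt = NA_REAL;
    int action = NA_INTEGER;
    if (do_gate) {
      // critic carries a learned intercept in its final element, so the
      // reward expectation generalises across PFC states
      double V = arma::dot(critic.head(npfc), pfc) + critic(npfc);
      double rwd = correct ? 1.0 : 0.0;
      dlt = kappa * (rwd - V);
      critic.head(npfc) += alpha * dlt * pfc;
      critic(npfc) += alpha * dlt;
      double g = std::min(1.0, std::fabs(dlt));
      if (dlt > delta_tol) {         // strengthen current PFC pattern
        for (int j = 0; j < npfc; ++j)
          maint(j) = (pfc(j) > P.a_on) ? maintenance_gain : 0.0;
        action = 1;
      } else if (dlt < -delta_tol) { // destabilise, graded by |delta|,
        // with a dopamine-scaled exploration floor so that failed sorts
        // always trigger meaningful search
        double gd = std::min(1.0, std::max(g, kappa * gate_floor));
        gd = std::pow(gd, gate_power);  // supralinear DA effect on release
        maint *= (1.0 - gd);
        pnoise = noise.row(i).t() * (noise_sd * gd);
        if (kick_width > 0 && kick_width < npfc) {
          // focal kick: excite only the largest-magnitude components so a
          // single candidate pattern is sampled and recurrence completes it
          vec a = arma::abs(pnoise);
          arma::uvec ord2 = arma::sort_index(a, "descend");
          vec nz(npfc, arma::fill::zeros);
          for (int q = 0; q < kick_width; ++q) nz(ord2(q)) = a(ord2(q));
          pnoise = nz;
        }
        action = -1;
      } else {
        action = 0;
      }
    }
    delta_out[i] = dlt; act_out[i] = action;
  }
  List wout = R_NilValue;
  if (do_learn) {
    // same order as build_xt_network()
    wout = List::create(
      _["in1_hid"] = wrap(W.i1h), _["in2_hid"] = wrap(W.i2h),
      _["task_hid"] = wrap(W.th), _["pfc_hid"] = wrap(W.ph),
      _["hid_resp"] = wrap(W.hr),
      _["in1_resp"] = wrap(W.ir1), _["in2_resp"] = wrap(W.ir2),
      _["pfc_resp"] = wrap(W.pr), _["resp_resp"] = wrap(W.rr),
      _["resp_hid"] = wrap(W.rh),
      _["hid_pfc"] = wrap(W.hp), _["task_pfc"] = wrap(W.tp),
      _["cue_pfc"] = wrap(W.cp), _["pfc_pfc"] = wrap(W.pp));
  }
  return List::create(
    _["weights"] = wout,
    _["maintenance"] = wrap(maint),
    _["noise_pending"] = wrap(pnoise),
    _["critic"] = wrap(critic),
    _["correct"] = corr_out,
    _["response"] = resp_out,
    _["cycles"] = cyc_out,
    _["label_cycles"] = lab_out,
    _["converged"] = conv_out,
    _["delta"] = delta_out,
    _["action"] = act_out,
    _["hidden"] = wrap(hid),
    _["pfc"] = wrap(pfc),
    _["resp"] = wrap(resp));
}
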