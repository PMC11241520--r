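// Operator-split integration core for the single-compartment DSM cell model.
//
// Per step (frozen-coefficient splitting at the model's native dt):
//   1. calcium pool      : exact exponential update at frozen Ca influx
//   2. HH gates          : exact exponential relaxation at frozen (v, cai)
//   3. BK Markov chain   : exact matrix-exponential propagation at frozen
//                          (v, cai) -- unconditionally stable for the stiff
//                          generator (rates span ~1e-3 .. ~1e3 / ms)
//   4. membrane voltage  : backward Euler on the (linear-in-v) current sum
//                          with the updated conductances
// Everything is deterministic; identical inputs give bit-identical output.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double FARADAY_C = 96485.33212;

// channel matrix column layout (see pack_model in R/model.R)
enum { C_GMAX = 0, C_EREV, C_CACARRY, C_ACT };
// per-gate block: kind, vh, slope, tau0, power, cahalf, hilln, tab_id
static const int GB = 8;

struct TauTable {
  std::vector<double> v, tau;
};

static inline double tau_interp(const TauTable &tt, double v) {
  const size_t n = tt.v.size();
  if (v <= tt.v[0]) return tt.tau[0];
  if (v >= tt.v[n - 1]) return tt.tau[n - 1];
  size_t hi = 1;
  while (tt.v[hi] < v) ++hi;
  double w = (v - tt.v[hi - 1]) / (tt.v[hi] - tt.v[hi - 1]);
  return tt.tau[hi - 1] + w * (tt.tau[hi] - tt.tau[hi - 1]);
}

static inline double gate_inf_c(int kind, double vh, double s, double ch,
                                double n, double v, double cai) {
  if (kind == 1) return 1.0 / (1.0 + std::exp((v + vh) / s));
  if (kind == 2) return cai <= 0.0 ? 0.0 : 1.0 / (1.0 + std::pow(ch / cai, n));
  return 1.0;
}

static inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

static void bk_generator(arma::mat &Q, const arma::vec &bk, double v,
                         double cai) {
  Q.zeros();
  const double kon = bk[2], kcoff = bk[3], kooff = bk[4];
  const double a = std::exp(v / bk[15]);
  const double b = std::exp(-v / bk[16]);
  // printed form: unbinding rates and K_O4C4 carry the published cai factor
  const double caf = bk[22] != 0.0 ? cai : 1.0;
  static const double up[4] = {3, 4, 3, 1};
  static const double dn[4] = {1, 3, 4, 3};
  for (int i = 0; i < 4; ++i) {
    Q(i, i + 1) = up[i] * kon * cai;
    Q(i + 5, i + 6) = up[i] * kon * cai;
    Q(i + 1, i) = dn[i] * kcoff * caf;
    Q(i + 6, i + 5) = dn[i] * kooff * caf;
  }
  for (int i = 0; i < 5; ++i) {
    Q(i, i + 5) = bk[5 + i] * a;
    double back = bk[10 + i] * b;
    if (i == 4) back *= caf;  // K_O4C4 cai factor in the printed form
    Q(i + 5, i) = back;
  }
  for (int i = 0; i < 10; ++i) Q(i, i) = -arma::accu(Q.row(i));
}

static void bk_advance(arma::vec &p, const arma::mat &Q, double dt) {
  arma::mat E = arma::expmat(Q.t() * dt);
  p = E * p;
  for (int i = 0; i < 10; ++i) if (p[i] < 0.0) p[i] = 0.0;
  p /= arma::accu(p);
}

// [[Rcpp::export]]
arma::vec bk_expm_step(const arma::mat &Q, const arma::vec &p0, double dt) {
  arma::vec p = p0;
  arma::mat Qc = Q;
  bk_advance(p, Qc, dt);
  return p;
}

// [[Rcpp::export]]
List dsm_run_core(const arma::mat &chan, const List &tau_tables,
                  const arma::vec &bk, const arma::vec &cap,
                  double c_specific, double area_cm2,
                  const arma::vec &stim,
                  double v0, double cai0, const arma::mat &gates0,
                  const arma::vec &bk0,
                  double t0, double dt, int n_steps, int record_every) {
  const int nchan = chan.n_rows;
  if (dt <= 0.0) stop("dt must be positive");
  if (n_steps < 0) stop("n_steps must be non-negative");
  if (record_every < 1) record_every = 1;

  std::vector<TauTable> tabs(tau_tables.size());
  for (int i = 0; i < tau_tables.size(); ++i) {
    List tt = tau_tables[i];
    tabs[i].v = as<std::vector<double>>(tt["v"]);
    tabs[i].tau = as<std::vector<double>>(tt["tau"]);
  }

  const double ca_rest = cap[0], tau_rem = cap[1];
  const double depth_cm = cap[2] * 1e-4;
  const bool ca_clamp = cap[3] != 0.0;
  const double ca_factor = 1e-3 / (2.0 * FARADAY_C * depth_cm);

  const int stim_kind = (int)stim[0];
  const double cdt = c_specific / dt;

  // working state
  double v = v0, cai = cai0;
  arma::mat g = gates0;  // 2 x nchan (activation; inactivation)
  arma::vec p = bk0;     // BK occupancy
  const double gbk_max = bk[0], e_bk = bk[1];
  arma::vec conducting = bk.subvec(17, 21);
  const bool bk_active = gbk_max > 0.0;
  arma::mat Q(10, 10);

  const int n_rec = n_steps / record_every + 1;
  NumericVector out_t(n_rec), out_v(n_rec), out_cai(n_rec), out_bko(n_rec),
      out_stim(n_rec);
  NumericMatrix out_i(n_rec, nchan + 1);  // per-channel + BK, uA/cm^2

  // per-channel conductance (S/cm^2) and current at a given v
  std::vector<double> gch(nchan);
  auto channel_conductances = [&](void) {
    for (int c = 0; c < nchan; ++c) {
      double f = 1.0;
      for (int gi = 0; gi < 2; ++gi) {
        const int base = C_ACT + gi * GB;
        const int kind = (int)chan(c, base);
        if (kind != 0) f *= ipow(g(gi, c), (int)chan(c, base + 4));
      }
      gch[c] = chan(c, C_GMAX) * f;
    }
  };

  double bko = 0.0;
  auto record = [&](int idx, double t_now) {
    out_t[idx] = t_now;
    out_v[idx] = v;
    out_cai[idx] = cai;
    channel_conductances();
    for (int c = 0; c < nchan; ++c)
      out_i(idx, c) = 1e3 * gch[c] * (v - chan(c, C_EREV));
    bko = arma::dot(p.subvec(5, 9), conducting);
    out_i(idx, nchan) = 1e3 * gbk_max * bko * (v - e_bk);
    out_bko[idx] = bko;
    double istim = 0.0;
    if (stim_kind == 1) {
      if (t_now >= stim[2] && t_now < stim[2] + stim[3]) istim = stim[1];
    } else if (stim_kind == 2) {
      double x = (t_now - stim[4]) / stim[2];
      if (x > 0.0) istim = stim[1] * x * std::exp(1.0 - x) * (v - stim[3]);
    }
    out_stim[idx] = istim;  // nA at the whole-cell level
  };

  record(0, t0);
  int rec_idx = 1;

  for (int k = 0; k < n_steps; ++k) {
    const double t_new = t0 + (k + 1) * dt;

    // (1) calcium pool at frozen influx (computed from the current state);
    //     gates and BK below relax toward targets at the pre-step calcium
    const double cai_pre = cai;
    if (ca_clamp) {
      cai = ca_rest;
    } else {
      channel_conductances();
      double ica = 0.0;
      for (int c = 0; c < nchan; ++c)
        if (chan(c, C_CACARRY) != 0.0)
          ica += 1e3 * gch[c] * (v - chan(c, C_EREV));
      const double ca_inf = ca_rest + tau_rem * (-ica) * ca_factor;
      cai = ca_inf + (cai_pre - ca_inf) * std::exp(-dt / tau_rem);
      if (cai < 1e-9) cai = 1e-9;
    }

    // (2) HH gates: exponential relaxation at frozen (v, cai_pre)
    for (int c = 0; c < nchan; ++c) {
      for (int gi = 0; gi < 2; ++gi) {
        const int base = C_ACT + gi * GB;
        const int kind = (int)chan(c, base);
        if (kind == 0) continue;
        const double inf = gate_inf_c(kind, chan(c, base + 1),
                                      chan(c, base + 2), chan(c, base + 5),
                                      chan(c, base + 6), v, cai_pre);
        double tau = chan(c, base + 3);
        const int tid = (int)chan(c, base + 7);
        if (tid >= 0) tau = tau_interp(tabs[tid], v);
        g(gi, c) = inf + (g(gi, c) - inf) * std::exp(-dt / tau);
      }
    }

    // (3) BK occupancy: exact propagation at frozen (v, cai)
    if (bk_active) {
      bk_generator(Q, bk, v, cai_pre);
      bk_advance(p, Q, dt);
    }

    // (4) membrane voltage: backward Euler with updated conductances
    channel_conductances();
    double gsum = 0.0, gesum = 0.0;
    for (int c = 0; c < nchan; ++c) {
      gsum += gch[c];
      gesum += gch[c] * chan(c, C_EREV);
    }
    bko = arma::dot(p.subvec(5, 9), conducting);
    const double gbk = gbk_max * bko;
    gsum += gbk;
    gesum += gbk * e_bk;
    double ipulse_d = 0.0, gsyn_d = 0.0, e_syn = 0.0;
    if (stim_kind == 1) {
      if (t_new >= stim[2] && t_new < stim[2] + stim[3])
        ipulse_d = stim[1] * 1e-3 / area_cm2;  // nA -> uA/cm^2
    } else if (stim_kind == 2) {
      const double x = (t_new - stim[4]) / stim[2];
      if (x > 0.0) {
        gsyn_d = stim[1] * 1e-6 / area_cm2 * x * std::exp(1.0 - x);
        e_syn = stim[3];
      }
    }
    v = (cdt * v + 1e3 * (gesum + gsyn_d * e_syn) + ipulse_d) /
        (cdt + 1e3 * (gsum + gsyn_d));

    if (!std::isfinite(v) || std::fabs(v) > 200.0) {
      stop("integration failure at step %d (t = %.3f ms): |v| exceeded 200 mV",
           k + 1, t_new);
    }

    if ((k + 1) % record_every == 0) {
      record(rec_idx, t_new);
      ++rec_idx;
    }
  }

  NumericMatrix gates_out(2, nchan);
  for (int c = 0; c < nchan; ++c) {
    gates_out(0, c) = g(0, c);
    gates_out(1, c) = g(1, c);
  }
  return List::create(
      _["t"] = out_t, _["v"] = out_v, _["cai"] = out_cai,
      _["i"] = out_i, _["bk_open"] = out_bko, _["i_stim"] = out_stim,
      _["state"] = List::create(_["v"] = v, _["cai"] = cai,
                                _["gates"] = gates_out,
                                _["bk"] = NumericVector(p.begin(), p.end()),
                                _["t"] = t0 + n_steps * dt));
}
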