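// Fixed-step RK4 kernels for the DA neuron and the Wang-Buzsaki GABA
// population.  The vector fields mirror the R implementations in R/rhs.R
// exactly (the test suite cross-checks them against deSolve/lsoda).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (exp(x) - 1), continuous at 0
static inline double xexpm1(double x) {
  if (std::fabs(x) < 1e-12) return 1.0;
  return x / std::expm1(x);
}

struct DAParams {
  double cm, gca, gkca, gk, gsna, gna, gdr, gl, gh;
  double eca, ek, ena, el, eh;
  double mg, me, ca_leak_frac, vhalf_ca, k_ca, ksk;
  double ca_gain, ca_pump;
  bool spike_cur, sna, ih, ca_leak;
};

static DAParams unpack(const NumericVector& p, const NumericVector& fl) {
  DAParams d;
  d.cm = p[0]; d.gca = p[1]; d.gkca = p[2]; d.gk = p[3]; d.gsna = p[4];
  d.gna = p[5]; d.gdr = p[6]; d.gl = p[7]; d.gh = p[8];
  d.eca = p[9]; d.ek = p[10]; d.ena = p[11]; d.el = p[12]; d.eh = p[13];
  d.mg = p[14]; d.me = p[15]; d.ca_leak_frac = p[16]; d.vhalf_ca = p[17];
  d.k_ca = p[18]; d.ksk = p[19]; d.ca_gain = p[20]; d.ca_pump = p[21];
  d.spike_cur = fl[0] != 0; d.sna = fl[1] != 0;
  d.ih = fl[2] != 0; d.ca_leak = fl[3] != 0;
  return d;
}

// dy/dt for state y = (v, ca, q, h, n); gn/ga/gg are effective synaptic
// conductances (gbar * gate) of NMDA/AMPA/GABA at this instant.
static inline void da_deriv(const double* y, const DAParams& p,
                            double gn, double ga, double gg,
                            double e_ampa, double e_gaba,
                            double iapp, double* dy) {
  const double v = y[0], ca = y[1], q = y[2], h = y[3], n = y[4];
  const double g_ca = p.gca / (1.0 + std::exp(-(v - p.vhalf_ca) / p.k_ca));
  const double ca4 = ca * ca * ca * ca;
  const double k4 = p.ksk * p.ksk * p.ksk * p.ksk;
  const double g_sk = p.gkca * ca4 / (ca4 + k4);
  const double g_k = p.gk / (1.0 + std::exp(-(v + 10.0) / 7.0));

  double iv = g_ca * (p.eca - v) + (g_sk + g_k) * (p.ek - v) +
    p.gl * (p.el - v);
  if (p.sna) iv += p.gsna / (1.0 + std::exp(-(v + 50.0) / 5.0)) * (p.ena - v);

  const double am = 1.28 * xexpm1(-(v + 39.0) / 4.0);
  const double bm = 1.40 * xexpm1((v + 4.0) / 5.0);
  const double ah = 0.01 * std::exp(-(v + 47.0) / 18.0);
  const double bh = 1.25 / (1.0 + std::exp(-(v + 24.0) / 5.0));
  const double an = 0.032 * xexpm1(-(v + 5.0) / 10.0);
  const double bn = 0.05 * std::exp(-(v + 10.0) / 16.0);
  if (p.spike_cur) {
    const double minf = am / (am + bm);
    iv += p.gna * minf * minf * minf * h * (p.ena - v) +
      p.gdr * n * n * n * n * (p.ek - v);
  }

  const double qinf = 1.0 / (1.0 + std::exp((v + 95.0) / 8.0));
  const double tauq = 625.0 * std::exp(0.075 * (v + 112.0)) /
    (1.0 + std::exp(0.083 * (v + 112.0)));
  if (p.ih) iv += p.gh * q * (p.eh - v);

  const double g_nmda_v = gn / (1.0 + 0.1 * p.mg * std::exp(-p.me * v));
  iv += g_nmda_v * (0.0 - v) + ga * (e_ampa - v) + gg * (e_gaba - v) + iapp;

  double g_in = g_ca + (p.ca_leak ? p.ca_leak_frac * p.gl : 0.0);
  dy[0] = iv / p.cm;
  dy[1] = p.ca_gain * g_in * (p.eca - v) - p.ca_pump * ca;
  dy[2] = (qinf - q) / tauq;
  dy[3] = ah * (1.0 - h) - bh * h;
  dy[4] = an * (1.0 - n) - bn * n;
}

static inline double drive_at(const NumericVector& x, R_xlen_t k) {
  return (x.size() == 1) ? x[0] : x[k];
}

// [[Rcpp::export(name = ".sim_da_cpp")]]
List sim_da_cpp(NumericVector state0, NumericVector params,
                NumericVector flags, double spike_threshold,
                double refractory, double duration, double dt,
                NumericVector gnmda, NumericVector gampa,
                NumericVector ggaba, NumericVector iapp,
                double e_ampa, double e_gaba, int record_every) {
  const DAParams p = unpack(params, flags);
  const R_xlen_t nstep = (R_xlen_t) std::llround(duration / dt);
  for (const NumericVector* d : {&gnmda, &gampa, &ggaba, &iapp}) {
    if (d->size() != 1 && d->size() < nstep + 1)
      stop("time-varying drive must have length >= nstep + 1");
  }
  double y[5], k1[5], k2[5], k3[5], k4[5], ym[5];
  for (int i = 0; i < 5; ++i) y[i] = state0[i];

  const R_xlen_t nrec = record_every > 0 ? nstep / record_every + 1 : 0;
  NumericVector tr_t(nrec), tr_v(nrec), tr_ca(nrec), tr_q(nrec),
    tr_h(nrec), tr_n(nrec);
  std::vector<double> spikes;
  double last_spike = -1e18, vprev = y[0];
  bool failed = false;
  double fail_t = NA_REAL;
  R_xlen_t irec = 0;
  if (record_every > 0) {
    tr_t[0] = 0.0; tr_v[0] = y[0]; tr_ca[0] = y[1];
    tr_q[0] = y[2]; tr_h[0] = y[3]; tr_n[0] = y[4]; irec = 1;
  }

  for (R_xlen_t k = 0; k < nstep; ++k) {
    const double gn = drive_at(gnmda, k), ga = drive_at(gampa, k),
      gg = drive_at(ggaba, k), ia = drive_at(iapp, k);
    da_deriv(y, p, gn, ga, gg, e_ampa, e_gaba, ia, k1);
    for (int i = 0; i < 5; ++i) ym[i] = y[i] + 0.5 * dt * k1[i];
    da_deriv(ym, p, gn, ga, gg, e_ampa, e_gaba, ia, k2);
    for (int i = 0; i < 5; ++i) ym[i] = y[i] + 0.5 * dt * k2[i];
    da_deriv(ym, p, gn, ga, gg, e_ampa, e_gaba, ia, k3);
    for (int i = 0; i < 5; ++i) ym[i] = y[i] + dt * k3[i];
    da_deriv(ym, p, gn, ga, gg, e_ampa, e_gaba, ia, k4);
    for (int i = 0; i < 5; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // keep gates and Ca2+ in their physical ranges (guards round-off only)
    if (y[1] < 0) y[1] = 0;
    for (int i = 2; i < 5; ++i) {
      if (y[i] < 0) y[i] = 0;
      if (y[i] > 1) y[i] = 1;
    }
    const double t = (k + 1) * dt;
    if (!std::isfinite(y[0]) || !std::isfinite(y[1])) {
      failed = true; fail_t = t;
      break;
    }
    if (vprev < spike_threshold && y[0] >= spike_threshold &&
        t - last_spike >= refractory) {
      // linear interpolation of the upcrossing time
      const double frac = (spike_threshold - vprev) / (y[0] - vprev);
      spikes.push_back(t - dt + frac * dt);
      last_spike = t;
    }
    vprev = y[0];
    if (record_every > 0 && (k + 1) % record_every == 0 && irec < nrec) {
      tr_t[irec] = t; tr_v[irec] = y[0]; tr_ca[irec] = y[1];
      tr_q[irec] = y[2]; tr_h[irec] = y[3]; tr_n[irec] = y[4]; ++irec;
    }
  }

  return List::create(
    _["time"] = tr_t, _["v"] = tr_v, _["ca"] = tr_ca,
    _["q"] = tr_q, _["h"] = tr_h, _["n"] = tr_n,
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["final_state"] = NumericVector::create(y[0], y[1], y[2], y[3], y[4]),
    _["failed"] = failed, _["fail_time"] = fail_t);
}

// Wang-Buzsaki derivative for one neuron, y = (v, h, n)
static inline void wb_deriv(const double* y, const NumericVector& p,
                            double iapp, double* dy) {
  const double v = y[0], h = y[1], n = y[2];
  const double am = 1.0 * xexpm1(-(v + 30.0) / 10.0);
  const double bm = 4.0 * std::exp(-(v + 55.0) / 18.0);
  const double ah = 0.07 * std::exp(-(v + 53.0) / 20.0);
  const double bh = 1.0 / (1.0 + std::exp(-(v + 23.0) / 10.0));
  const double an = 0.1 * xexpm1(-(v + 29.0) / 10.0);
  const double bn = 0.0875 * std::exp(-(v + 39.0) / 80.0);
  const double minf = am / (am + bm);
  const double iv = p[1] * minf * minf * minf * h * (p[4] - v) +
    p[2] * n * n * n * n * (p[5] - v) + p[3] * (p[6] - v) + iapp;
  dy[0] = iv / p[0];
  dy[1] = ah * (1.0 - h) - bh * h;
  dy[2] = an * (1.0 - n) - bn * n;
}

// Integrates n GABA neurons plus their receptor gates driven by
// gspike(v) = 1/(1+exp(-v/2)); returns the population-mean gate sampled
// every record_every steps, per-neuron spike times, and spike counts.
// [[Rcpp::export(name = ".sim_gaba_pop_cpp")]]
List sim_gaba_pop_cpp(NumericMatrix state0, NumericVector params,
                      NumericVector iapp, double duration, double dt,
                      double tau_act, double tau_deact,
                      double spike_threshold, double refractory,
                      int record_every) {
  const int nn = state0.nrow();
  const R_xlen_t nstep = (R_xlen_t) std::llround(duration / dt);
  const R_xlen_t nrec = nstep / record_every + 1;
  NumericVector tr_t(nrec), s_mean(nrec);
  NumericMatrix y(nn, 3);
  std::vector<double> s(nn, 0.0), vprev(nn), last_spike(nn, -1e18);
  std::vector<std::vector<double>> spikes(nn);
  for (int j = 0; j < nn; ++j) {
    for (int i = 0; i < 3; ++i) y(j, i) = state0(j, i);
    vprev[j] = y(j, 0);
  }
  tr_t[0] = 0.0; s_mean[0] = 0.0;
  R_xlen_t irec = 1;
  double k1[3], k2[3], k3[3], k4[3], ym[3], yy[3];

  for (R_xlen_t k = 0; k < nstep; ++k) {
    const double t = (k + 1) * dt;
    double ssum = 0.0;
    for (int j = 0; j < nn; ++j) {
      for (int i = 0; i < 3; ++i) yy[i] = y(j, i);
      wb_deriv(yy, params, iapp[j], k1);
      for (int i = 0; i < 3; ++i) ym[i] = yy[i] + 0.5 * dt * k1[i];
      wb_deriv(ym, params, iapp[j], k2);
      for (int i = 0; i < 3; ++i) ym[i] = yy[i] + 0.5 * dt * k2[i];
      wb_deriv(ym, params, iapp[j], k3);
      for (int i = 0; i < 3; ++i) ym[i] = yy[i] + dt * k3[i];
      wb_deriv(ym, params, iapp[j], k4);
      for (int i = 0; i < 3; ++i)
        yy[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      for (int i = 1; i < 3; ++i) {
        if (yy[i] < 0) yy[i] = 0;
        if (yy[i] > 1) yy[i] = 1;
      }
      // receptor gate, forward-Euler on the gspike-driven kinetics
      const double gs = 1.0 / (1.0 + std::exp(-yy[0] / 2.0));
      s[j] += dt * (gs * (1.0 - s[j]) / tau_act -
                    (1.0 - gs) * s[j] / tau_deact);
      if (s[j] < 0) s[j] = 0;
      if (s[j] > 1) s[j] = 1;
      if (vprev[j] < spike_threshold && yy[0] >= spike_threshold &&
          t - last_spike[j] >= refractory) {
        spikes[j].push_back(t);
        last_spike[j] = t;
      }
      vprev[j] = yy[0];
      for (int i = 0; i < 3; ++i) y(j, i) = yy[i];
      ssum += s[j];
    }
    if ((k + 1) % record_every == 0 && irec < nrec) {
      tr_t[irec] = t;
      s_mean[irec] = ssum / nn;
      ++irec;
    }
  }
  List sp(nn);
  for (int j = 0; j < nn; ++j)
    sp[j] = NumericVector(spikes[j].begin(), spikes[j].end());
  return List::create(_["time"] = tr_t, _["s_gaba"] = s_mean,
                      _["spikes"] = sp, _["final_state"] = y);
}

// Exact branchwise update of a receptor gate driven by a binary input
// j(t): ds/dt = j (1-s)/tau_act - (1-j) s/tau_deact, integrated exactly
// over each dt on which j is constant.
// [[Rcpp::export(name = ".gate_from_drive_cpp")]]
NumericVector gate_from_drive_cpp(NumericVector j, double dt,
                                  double tau_act, double tau_deact,
                                  double s0) {
  const R_xlen_t n = j.size();
  NumericVector s(n + 1);
  s[0] = s0;
  const double ea = std::exp(-dt / tau_act);
  const double ed = std::exp(-dt / tau_deact);
  for (R_xlen_t k = 0; k < n; ++k) {
    s[k + 1] = (j[k] > 0.5) ? 1.0 - (1.0 - s[k]) * ea : s[k] * ed;
  }
  return s;
}

// Michaelis-Menten dopamine release/uptake driven by pooled spike times:
// d[DA]/dt = -Vmax [DA]/(Km + [DA]) between spikes, +DAmax per spike.
// [[Rcpp::export(name = ".da_release_cpp")]]
NumericVector da_release_cpp(NumericVector spikes, double duration,
                             double dt, double da_max, double v_max,
                             double k_m, double da0) {
  const R_xlen_t nstep = (R_xlen_t) std::llround(duration / dt);
  NumericVector da(nstep + 1);
  da[0] = da0;
  double x = da0;
  R_xlen_t isp = 0;
  const R_xlen_t nsp = spikes.size();
  for (R_xlen_t k = 0; k < nstep; ++k) {
    const double t1 = (k + 1) * dt;
    while (isp < nsp && spikes[isp] <= t1) {
      x += da_max;
      ++isp;
    }
    // RK4 on the uptake term
    const double f1 = -v_max * x / (k_m + x);
    double xm = x + 0.5 * dt * f1;
    const double f2 = -v_max * xm / (k_m + xm);
    xm = x + 0.5 * dt * f2;
    const double f3 = -v_max * xm / (k_m + xm);
    xm = x + dt * f3;
    const double f4 = -v_max * xm / (k_m + xm);
    x += dt / 6.0 * (f1 + 2.0 * f2 + 2.0 * f3 + f4);
    if (x < 0) x = 0;
    da[k + 1] = x;
  }
  return da;
}
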