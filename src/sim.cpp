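// Core integrators: the conductance-based spiking network and the 2D
// Langevin surrogates. Both use per-stream RNG seeded from a single master
// seed so results are independent of loop order and reproducible.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct ClassPars {
  double Cm, gL, VL, Vth, Vreset, tref;
};

inline double nmda_gate(double v, double Mg) {
  return 1.0 / (1.0 + Mg * std::exp(-0.062 * v) / 3.57);
}

// Tabulated magnesium gate with linear interpolation on a 0.01 mV grid;
// interpolation error ~5e-8, far below the dt-discretization error.
struct GateTable {
  static constexpr double lo = -120.0, hi = 20.0, h = 0.01;
  std::vector<double> tab;
  double Mg_;
  explicit GateTable(double Mg) : Mg_(Mg) {
    int n = (int)((hi - lo) / h) + 2;
    tab.resize(n);
    for (int i = 0; i < n; ++i) tab[i] = nmda_gate(lo + i * h, Mg);
  }
  inline double operator()(double v) const {
    if (v < lo || v > hi) return nmda_gate(v, Mg_);
    double u = (v - lo) / h;
    int i = (int)u;
    double f = u - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

// Knuth small-mean Poisson sampler with the exp(-mean) factor precomputed.
struct PoisSmall {
  double L;
  PoisSmall() : L(1.0) {}
  explicit PoisSmall(double mean) : L(std::exp(-mean)) {}
  inline int draw(std::mt19937_64 &e) const {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    int k = 0;
    double p = U(e);
    while (p > L) { ++k; p *= U(e); }
    return k;
  }
};

} // namespace

// Simulate the four-population (S1, S2, NS, I) fully connected network.
// Populations are laid out contiguously: S1, S2, NS (excitatory), then I.
// Units: time ms, voltage mV, capacitance nF, conductance nS (converted to
// uS internally so currents come out in nA), rates in events/ms.
//
// The smooth parts of the membrane and gating equations take a Heun
// (second-order Runge-Kutta) step; delta-function inputs (recurrent spikes
// and Poisson arrivals) are applied as unit jumps between steps. Spikes are
// detected at step boundaries; a spiking neuron is clamped to Vreset for
// its refractory period and its outgoing gating jumps land on the next step.
// [[Rcpp::export]]
List sim_network_cpp(int N_S1, int N_S2, int N_NS, int N_I,
                     NumericMatrix W,          // 4x4 weights, [pre, post], AMPA+NMDA sums
                     NumericVector exc_pars,   // Cm,gL,VL,Vth,Vreset,tref
                     NumericVector inh_pars,
                     NumericVector g_exc,      // g_ext_AMPA, g_rec_AMPA, g_NMDA, g_GABA (nS, onto E)
                     NumericVector g_inh,      // same, onto I
                     double tauA, double tauNd, double tauNr, double tauG,
                     double alpha, double Mg, double VE, double VI,
                     double v_ext_khz,         // background Poisson, kHz per neuron
                     NumericMatrix stim,       // columns t_from_ms, mu1_hz, mu2_hz; rows ascending
                     double I_inject, double inj_on, double inj_off,
                     double dt, double duration_ms, int seed,
                     bool record_spikes, double count_bin_ms, int gating_stride) {
  const int NE = N_S1 + N_S2 + N_NS;
  const int N = NE + N_I;
  if (N <= 0) stop("empty network");
  const int n_steps = (int)std::llround(duration_ms / dt);

  ClassPars exc = {exc_pars[0], exc_pars[1] * 1e-3, exc_pars[2], exc_pars[3],
                   exc_pars[4], exc_pars[5]};
  ClassPars inh = {inh_pars[0], inh_pars[1] * 1e-3, inh_pars[2], inh_pars[3],
                   inh_pars[4], inh_pars[5]};
  // conductances nS -> uS so g * mV = nA
  double gE[4], gI[4];
  for (int k = 0; k < 4; ++k) { gE[k] = g_exc[k] * 1e-3; gI[k] = g_inh[k] * 1e-3; }

  // population membership boundaries
  auto pop_of = [&](int i) {
    if (i < N_S1) return 0;
    if (i < N_S1 + N_S2) return 1;
    if (i < NE) return 2;
    return 3;
  };

  std::vector<double> V(N), ref_until(N, -1e18), s_ext(N, 0.0);
  std::vector<double> sa(NE, 0.0), sn(NE, 0.0), xn(NE, 0.0), sg(N_I, 0.0);
  std::vector<double> sa_p(NE), sn_p(NE), xn_p(NE), sg_p(N_I), se_p(N);
  std::vector<char> pending(N, 0);
  std::vector<int> pop(N);
  for (int i = 0; i < N; ++i) { pop[i] = pop_of(i); V[i] = (pop[i] == 3 ? inh.VL : exc.VL); }

  // per-neuron RNG streams: order-invariant, reproducible
  std::vector<std::mt19937_64> eng;
  eng.reserve(N);
  for (int i = 0; i < N; ++i) {
    std::seed_seq ss{seed, i, 0x5eed};
    eng.emplace_back(ss);
  }

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  if (record_spikes) { spike_id.reserve(1 << 16); spike_t.reserve(1 << 16); }

  int n_bins = 0;
  IntegerMatrix counts;
  if (count_bin_ms > 0) {
    n_bins = (int)std::ceil(duration_ms / count_bin_ms - 1e-9);
    counts = IntegerMatrix(n_bins, 4);
  }
  std::vector<double> trace_t;
  std::vector<std::array<double, 7>> trace; // SA0..2, SN0..2, SG
  double gating_min = 0.0, snmda_max = 0.0;

  const double v_ext = v_ext_khz;           // events per ms
  const PoisSmall pois_bg(v_ext * dt);
  const int n_seg = stim.nrow();
  std::vector<PoisSmall> pois_s1, pois_s2;
  for (int s = 0; s < n_seg; ++s) {
    pois_s1.emplace_back((v_ext + stim(s, 1) * 1e-3) * dt);
    pois_s2.emplace_back((v_ext + stim(s, 2) * 1e-3) * dt);
  }
  int seg = -1; // active stimulus segment, -1 = before the first
  const GateTable gate(Mg);

  double SA[3], SN[3], SA1[3], SN1[3], SG0 = 0.0, SG1 = 0.0;
  double WA[4], WN[4], WA1[4], WN1[4];

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    while (seg + 1 < n_seg && t >= stim(seg + 1, 0) - 1e-12) ++seg;
    const bool inj_now = (t >= inj_on && t < inj_off);
    const double Iinj = inj_now ? I_inject : 0.0;

    // 1) discrete jumps: recurrent spikes from previous step, Poisson arrivals
    for (int i = 0; i < N; ++i) {
      if (pending[i]) {
        if (i < NE) { sa[i] += 1.0; xn[i] += 1.0; }
        else sg[i - NE] += 1.0;
        pending[i] = 0;
      }
      const PoisSmall *ps = &pois_bg;
      if (seg >= 0) {
        if (pop[i] == 0) ps = &pois_s1[seg];
        else if (pop[i] == 1) ps = &pois_s2[seg];
      }
      if (ps->L < 1.0) {
        int k = ps->draw(eng[i]);
        if (k > 0) s_ext[i] += k;
      }
    }

    // 2) population gating sums (stage 1)
    SA[0] = SA[1] = SA[2] = SN[0] = SN[1] = SN[2] = 0.0; SG0 = 0.0;
    for (int j = 0; j < NE; ++j) { SA[pop[j]] += sa[j]; SN[pop[j]] += sn[j]; }
    for (int j = 0; j < N_I; ++j) SG0 += sg[j];
    for (int p = 0; p < 4; ++p) {
      WA[p] = W(0, p) * SA[0] + W(1, p) * SA[1] + W(2, p) * SA[2];
      WN[p] = W(0, p) * SN[0] + W(1, p) * SN[1] + W(2, p) * SN[2];
    }

    // 3) Heun stage 1: gating provisional values
    for (int j = 0; j < NE; ++j) {
      sa_p[j] = sa[j] + dt * (-sa[j] / tauA);
      xn_p[j] = xn[j] + dt * (-xn[j] / tauNr);
      sn_p[j] = sn[j] + dt * (-sn[j] / tauNd + alpha * xn[j] * (1.0 - sn[j]));
    }
    for (int j = 0; j < N_I; ++j) sg_p[j] = sg[j] + dt * (-sg[j] / tauG);
    for (int i = 0; i < N; ++i) se_p[i] = s_ext[i] + dt * (-s_ext[i] / tauA);

    SA1[0] = SA1[1] = SA1[2] = SN1[0] = SN1[1] = SN1[2] = 0.0; SG1 = 0.0;
    for (int j = 0; j < NE; ++j) { SA1[pop[j]] += sa_p[j]; SN1[pop[j]] += sn_p[j]; }
    for (int j = 0; j < N_I; ++j) SG1 += sg_p[j];
    for (int p = 0; p < 4; ++p) {
      WA1[p] = W(0, p) * SA1[0] + W(1, p) * SA1[1] + W(2, p) * SA1[2];
      WN1[p] = W(0, p) * SN1[0] + W(1, p) * SN1[1] + W(2, p) * SN1[2];
    }

    // 4) membrane potentials (Heun), spike detection at step end
    for (int i = 0; i < N; ++i) {
      const bool is_inh = (pop[i] == 3);
      const ClassPars &cp = is_inh ? inh : exc;
      if (t < ref_until[i] - 1e-12) { V[i] = cp.Vreset; continue; }
      const double *g = is_inh ? gI : gE;
      const int p = pop[i];
      double v = V[i];
      double d1 = (-cp.gL * (v - cp.VL)
                   - g[0] * (v - VE) * s_ext[i]
                   - g[1] * (v - VE) * WA[p]
                   - g[2] * (v - VE) * gate(v) * WN[p]
                   - g[3] * (v - VI) * SG0
                   - Iinj) / cp.Cm;
      double vp = v + dt * d1;
      double d2 = (-cp.gL * (vp - cp.VL)
                   - g[0] * (vp - VE) * se_p[i]
                   - g[1] * (vp - VE) * WA1[p]
                   - g[2] * (vp - VE) * gate(vp) * WN1[p]
                   - g[3] * (vp - VI) * SG1
                   - Iinj) / cp.Cm;
      double vn = v + 0.5 * dt * (d1 + d2);
      if (!std::isfinite(vn))
        stop("non-finite membrane potential at t = %f ms, neuron %d", t, i + 1);
      if (vn >= cp.Vth) {
        const double ts = t + dt;
        V[i] = cp.Vreset;
        ref_until[i] = ts + cp.tref;
        pending[i] = 1;
        if (record_spikes) { spike_id.push_back(i + 1); spike_t.push_back(ts); }
        if (n_bins > 0) {
          int b = (int)(ts / count_bin_ms - 1e-9);
          if (b >= n_bins) b = n_bins - 1;
          counts(b, p) += 1;
        }
      } else {
        V[i] = vn;
      }
    }

    // 5) gating final values (Heun average of stage derivatives)
    for (int j = 0; j < NE; ++j) {
      const double d1 = -sn[j] / tauNd + alpha * xn[j] * (1.0 - sn[j]);
      const double d2 = -sn_p[j] / tauNd + alpha * xn_p[j] * (1.0 - sn_p[j]);
      sa[j] += 0.5 * dt * (-sa[j] / tauA - sa_p[j] / tauA);
      xn[j] += 0.5 * dt * (-xn[j] / tauNr - xn_p[j] / tauNr);
      sn[j] += 0.5 * dt * (d1 + d2);
      if (sa[j] < gating_min) gating_min = sa[j];
      if (xn[j] < gating_min) gating_min = xn[j];
      if (sn[j] < gating_min) gating_min = sn[j];
      if (sn[j] > snmda_max) snmda_max = sn[j];
    }
    for (int j = 0; j < N_I; ++j) {
      sg[j] += 0.5 * dt * (-sg[j] / tauG - sg_p[j] / tauG);
      if (sg[j] < gating_min) gating_min = sg[j];
    }
    for (int i = 0; i < N; ++i)
      s_ext[i] += 0.5 * dt * (-s_ext[i] / tauA - se_p[i] / tauA);

    if (gating_stride > 0 && step % gating_stride == 0) {
      trace_t.push_back(t + dt);
      std::array<double, 7> row = {0, 0, 0, 0, 0, 0, 0};
      for (int j = 0; j < NE; ++j) { row[pop[j]] += sa[j]; row[3 + pop[j]] += sn[j]; }
      for (int j = 0; j < N_I; ++j) row[6] += sg[j];
      trace.push_back(row);
    }
  }

  List out = List::create(
      _["neuron"] = wrap(spike_id), _["time_ms"] = wrap(spike_t),
      _["counts"] = counts, _["count_bin_ms"] = count_bin_ms,
      _["gating_min"] = gating_min, _["snmda_max"] = snmda_max,
      _["duration_ms"] = n_steps * dt);
  if (gating_stride > 0) {
    int m = (int)trace.size();
    NumericMatrix tr(m, 8);
    for (int r = 0; r < m; ++r) {
      tr(r, 0) = trace_t[r];
      for (int c = 0; c < 7; ++c) tr(r, c + 1) = trace[r][c];
    }
    colnames(tr) = CharacterVector::create("t", "sA_S1", "sA_S2", "sA_NS",
                                           "sN_S1", "sN_S2", "sN_NS", "sG_I");
    out["gating"] = tr;
  }
  return out;
}

// Euler-Maruyama integration of a 2D Langevin system dx = F(x) dt + sqrt(2D) dW.
// family: 1 = double well, 2 = triple well (Gaussian wells + harmonic
// confinement), 3 = linear rotational (OU with antisymmetric drift part).
// [[Rcpp::export]]
List sim_langevin_cpp(int family, NumericVector pars, double D, double dt,
                      double duration, int sample_stride,
                      NumericVector x0, int seed) {
  const long n_steps = (long)std::llround(duration / dt);
  std::seed_seq ss{seed, 0x1a27e};
  std::mt19937_64 eng(ss);
  std::normal_distribution<double> norm(0.0, 1.0);
  const double sig = std::sqrt(2.0 * D * dt);

  double x = x0[0], y = x0[1];
  const long n_keep = n_steps / sample_stride;
  NumericVector ts(n_keep), xs(n_keep), ys(n_keep);
  long k = 0;

  // unpack drift parameters
  double a = 0, b = 0, h = 0, kk = 0, om = 0, A = 0, s2 = 0, conf = 0;
  double wx[3] = {0, 0, 0}, wy[3] = {0, 0, 0}, cx = 0, cy = 0;
  if (family == 1) { a = pars[0]; b = pars[1]; h = pars[2]; }
  else if (family == 2) {
    A = pars[0]; s2 = pars[1] * pars[1]; conf = pars[2];
    wx[0] = pars[3]; wy[0] = pars[4]; wx[1] = pars[5]; wy[1] = pars[6];
    wx[2] = pars[7]; wy[2] = pars[8]; cx = pars[9]; cy = pars[10];
  } else if (family == 3) { kk = pars[0]; om = pars[1]; }
  else stop("unknown drift family");

  for (long step = 0; step < n_steps; ++step) {
    double fx, fy;
    if (family == 1) {
      fx = -4.0 * a * x * (x * x - 1.0) - h;
      fy = -2.0 * b * y;
    } else if (family == 2) {
      fx = -conf * (x - cx); fy = -conf * (y - cy);
      for (int w = 0; w < 3; ++w) {
        double dxw = x - wx[w], dyw = y - wy[w];
        double g = A * std::exp(-(dxw * dxw + dyw * dyw) / (2.0 * s2));
        fx += -g * dxw / s2;
        fy += -g * dyw / s2;
      }
    } else {
      fx = -kk * x - om * y;
      fy = om * x - kk * y;
    }
    x += dt * fx + sig * norm(eng);
    y += dt * fy + sig * norm(eng);
    if (std::abs(x) > 1e8 || std::abs(y) > 1e8)
      stop("Langevin trajectory diverged at t = %f (dt too large for drift stiffness?)", step * dt);
    if ((step + 1) % sample_stride == 0 && k < n_keep) {
      ts[k] = (step + 1) * dt; xs[k] = x; ys[k] = y; ++k;
    }
  }
  return List::create(_["t"] = ts, _["x"] = xs, _["y"] = ys);
}
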