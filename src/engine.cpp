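// Fixed-step network integrator: Hodgkin-Huxley point neurons, kinetic
// AMPA/NMDA/GABA-A synapses with Tsodyks-Markram short-term plasticity,
// delayed spike delivery through a ring-buffer event queue, and
// Ornstein-Uhlenbeck point-conductance noise/stimulus drives.
//
// Units: time ms, voltage mV, conductance uS, current nA, capacitance nF.
//
// Numerical scheme: exponential Euler for gates and voltage at step dt;
// receptor gating and the OU drives are advanced on a coarser sub-grid
// (syn_stride * dt, default 0.2 ms) with conductances held in between --
// receptor and drive time constants (>= 2.7 ms except the x transient,
// which is handled by its exact within-interval integral) are well above
// that grid. Convergence is checked by halve_step_check().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

// -- fast exp: 2^n * poly(r), |rel err| < 1e-8 over the simulator's range
static inline double fexp(double x) {
  if (x > 700.0) x = 700.0;
  else if (x < -700.0) return 0.0;
  const double LOG2E = 1.4426950408889634;
  const double C1 = 6.93145751953125e-1;
  const double C2 = 1.42860682030941723212e-6;
  // round to nearest integer without std::floor (magic-number trick)
  const double MAGIC = 6755399441055744.0; // 1.5 * 2^52
  double n = (x * LOG2E + MAGIC) - MAGIC;
  double r = (x - n * C1) - n * C2;
  double r2 = r * r;
  double p = 1.0 + r + r2 * (0.5 + r * (1.0 / 6.0 + r * (1.0 / 24.0 +
             r * (1.0 / 120.0 + r * (1.0 / 720.0 + r * (1.0 / 5040.0))))));
  union { double d; uint64_t u; } v;
  v.d = p;
  v.u += ((uint64_t)(int64_t)n) << 52;
  return v.d;
}

// x / (exp(x) - 1), continuous through 0
static inline double xexprel(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 - 0.5 * x + x * x / 12.0;
  return x / (fexp(x) - 1.0);
}

// -- deterministic per-cell RNG (splitmix64 + Box-Muller) --------------------
static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct CellRng {
  uint64_t s = 0;
  bool has_spare = false;
  double spare = 0.0;
  double unif() {
    return (splitmix64_next(s) >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(NumericMatrix cell_par,   // cols: C,G_leak,E_leak,G_Na,E_Na,G_Kd,E_K,G_M,V_T,tau_max,V0
                     IntegerVector syn_pre,    // 0-based, sorted by pre
                     IntegerVector syn_post,
                     NumericVector syn_G,
                     IntegerVector syn_kin,    // 0 fast (AMPA/GABA), 1 NMDA
                     IntegerVector syn_bucket, // 0 exc, 1 nmda, 2 inh
                     NumericVector syn_E,
                     IntegerVector syn_delay,  // steps, >= 1
                     IntegerVector syn_stp,    // 0 none, 1 depressing, 2 facilitating
                     NumericVector syn_U,
                     NumericVector syn_U1,
                     NumericVector syn_tau_rec,
                     NumericVector syn_tau_facil,
                     IntegerVector adj_offset, // length ncell+1 into syn arrays
                     NumericVector noise_mean,
                     NumericVector noise_sd,
                     NumericVector stim_mean,
                     NumericVector stim_sd,
                     IntegerVector stim_on,
                     IntegerVector stim_off,
                     IntegerVector forced_cell, // 0-based, sorted by step
                     IntegerVector forced_step,
                     double dt, int n_steps, double seed,
                     double tau_noise, double mg, double lockout_ms,
                     IntegerVector record_cells, int record_stride,
                     int syn_stride = 4) {
  const int ncell = cell_par.nrow();
  const int nsyn = syn_pre.size();
  if (syn_stride < 1) syn_stride = 1;

  // cell parameters into flat arrays
  std::vector<double> pC(ncell), pGl(ncell), pEl(ncell), pGna(ncell),
      pEna(ncell), pGkd(ncell), pEk(ncell), pGm(ncell), pVt(ncell),
      pTaum(ncell);
  std::vector<double> V(ncell), m(ncell), h(ncell), n(ncell), p(ncell);
  std::vector<double> last_spike(ncell, -1e18);
  for (int i = 0; i < ncell; ++i) {
    pC[i] = cell_par(i, 0); pGl[i] = cell_par(i, 1); pEl[i] = cell_par(i, 2);
    pGna[i] = cell_par(i, 3); pEna[i] = cell_par(i, 4);
    pGkd[i] = cell_par(i, 5); pEk[i] = cell_par(i, 6);
    pGm[i] = cell_par(i, 7); pVt[i] = cell_par(i, 8);
    pTaum[i] = cell_par(i, 9);
    double v0 = cell_par(i, 10), vt = pVt[i];
    V[i] = v0;
    double am = 1.28 * xexprel(-(v0 - vt - 13.0) / 4.0);
    double bm = 1.40 * xexprel((v0 - vt - 40.0) / 5.0);
    double ah = 0.128 * std::exp(-(v0 - vt - 17.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(v0 - vt - 40.0) / 5.0));
    double an = 0.16 * xexprel(-(v0 - vt - 15.0) / 5.0);
    double bn = 0.5 * std::exp(-(v0 - vt - 10.0) / 40.0);
    m[i] = am / (am + bm);
    h[i] = ah / (ah + bh);
    n[i] = an / (an + bn);
    p[i] = 1.0 / (1.0 + std::exp(-(v0 + 35.0) / 10.0));
  }

  std::vector<CellRng> rng(ncell);
  uint64_t base = 0x9E3779B97F4A7C15ULL * (uint64_t)(seed + 1.0);
  for (int i = 0; i < ncell; ++i) {
    uint64_t st = base ^ (0xBF58476D1CE4E5B9ULL * (uint64_t)(i + 1));
    splitmix64_next(st); splitmix64_next(st);
    rng[i].s = st;
  }

  // synapse state
  std::vector<double> sx(nsyn, 0.0), ss(nsyn, 0.0);
  std::vector<double> stpR(nsyn, 1.0), stpu(nsyn, 0.0), stp_last(nsyn, -1e18);
  std::vector<char> active(nsyn, 0);
  std::vector<int> active_list;
  active_list.reserve(nsyn > 0 ? nsyn / 4 + 16 : 16);

  // kinetic constants per class (0 fast, 1 NMDA), on the synapse sub-grid
  const double dts = dt * syn_stride;
  const double tau_x[2] = {0.05, 5.0};
  const double tau_s[2] = {6.0, 150.0};
  double dec_x[2], dec_s[2], xint[2];
  for (int k = 0; k < 2; ++k) {
    dec_x[k] = std::exp(-dts / tau_x[k]);
    dec_s[k] = std::exp(-dts / tau_s[k]);
    xint[k] = tau_x[k] * (1.0 - dec_x[k]);
  }

  // event ring buffer
  int max_delay = 1;
  for (int i = 0; i < nsyn; ++i) if (syn_delay[i] > max_delay) max_delay = syn_delay[i];
  const int ring_n = max_delay + 2;
  std::vector<std::vector<int> > ring(ring_n);

  // drives, updated on the sub-grid
  std::vector<double> g_noise(ncell), g_stim(ncell);
  const double a_ou = std::exp(-dts / tau_noise);
  const double b_ou = std::sqrt(1.0 - a_ou * a_ou);
  for (int i = 0; i < ncell; ++i) {
    g_noise[i] = noise_mean[i];
    g_stim[i] = stim_mean[i];
  }
  std::vector<char> has_noise(ncell);
  for (int i = 0; i < ncell; ++i)
    has_noise[i] = (noise_mean[i] > 0.0 || noise_sd[i] > 0.0) ? 1 : 0;

  // per-cell synaptic conductance accumulators (held between sub-steps)
  std::vector<double> acc_e(ncell, 0.0), acc_nmda(ncell, 0.0),
      acc_i(ncell, 0.0), acc_iE(ncell, 0.0), g_drive(ncell, 0.0);
  for (int i = 0; i < ncell; ++i) g_drive[i] = has_noise[i] ? g_noise[i] : 0.0;

  // recording
  const int nrec = record_cells.size();
  int nsamp = (record_stride > 0 && nrec > 0) ? (n_steps / record_stride + 1) : 0;
  NumericMatrix vrec(nsamp, nrec);
  NumericVector vrec_t(nsamp);
  int samp = 0;
  if (nsamp > 0) {
    for (int j = 0; j < nrec; ++j) vrec(0, j) = V[record_cells[j]];
    vrec_t[0] = 0.0;
    samp = 1;
  }

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  double delivered = 0.0;
  int fptr = 0;
  const int nforced = forced_cell.size();

  for (int t = 1; t <= n_steps; ++t) {
    const double t_ms = t * dt;
    const int slot = t % ring_n;

    // forced presynaptic spikes scheduled for this step
    while (fptr < nforced && forced_step[fptr] == t) {
      int c = forced_cell[fptr];
      for (int k = adj_offset[c]; k < adj_offset[c + 1]; ++k)
        ring[(t + syn_delay[k]) % ring_n].push_back(k);
      ++fptr;
    }

    // deliver arrivals: STP event then gating increment
    std::vector<int> &arr = ring[slot];
    if (!arr.empty()) {
      delivered += (double)arr.size();
      for (size_t q = 0; q < arr.size(); ++q) {
        int i = arr[q];
        double rel;
        int mode = syn_stp[i];
        if (mode == 0) {
          rel = 1.0;
        } else {
          double R = stpR[i], u = stpu[i];
          if (stp_last[i] > -1e17) {
            double del = t_ms - stp_last[i];
            R = 1.0 - (1.0 - R) * fexp(-del / syn_tau_rec[i]);
            if (mode == 2 && syn_tau_facil[i] > 0)
              u *= fexp(-del / syn_tau_facil[i]);
          }
          if (mode == 2) {
            u += syn_U1[i] * (1.0 - u);
            rel = u * R;
          } else {
            rel = syn_U[i] * R;
          }
          R -= rel;
          stpR[i] = R; stpu[i] = u; stp_last[i] = t_ms;
        }
        sx[i] += rel; // alpha_x = 1
        if (!active[i]) { active[i] = 1; active_list.push_back(i); }
      }
      arr.clear();
    }

    // synapse + drive sub-grid
    if (t % syn_stride == 0) {
      std::memset(acc_e.data(), 0, ncell * sizeof(double));
      std::memset(acc_nmda.data(), 0, ncell * sizeof(double));
      std::memset(acc_i.data(), 0, ncell * sizeof(double));
      std::memset(acc_iE.data(), 0, ncell * sizeof(double));
      for (size_t q = 0; q < active_list.size();) {
        int i = active_list[q];
        int k = syn_kin[i];
        double x = sx[i], s = ss[i];
        s = s * dec_s[k] + x * xint[k] * (1.0 - s);
        if (s > 1.0) s = 1.0;
        x *= dec_x[k];
        sx[i] = x; ss[i] = s;
        if (x < 1e-6 && s < 1e-6) {
          sx[i] = 0.0; ss[i] = 0.0;
          active[i] = 0;
          active_list[q] = active_list.back();
          active_list.pop_back();
          continue;
        }
        double gc = syn_G[i] * s;
        int b = syn_bucket[i], post = syn_post[i];
        if (b == 0) acc_e[post] += gc;
        else if (b == 1) acc_nmda[post] += gc;
        else { acc_i[post] += gc; acc_iE[post] += gc * syn_E[i]; }
        ++q;
      }
      for (int i = 0; i < ncell; ++i) {
        double gd = 0.0;
        if (has_noise[i]) {
          double gn = noise_mean[i] + (g_noise[i] - noise_mean[i]) * a_ou;
          if (noise_sd[i] > 0.0) gn += noise_sd[i] * b_ou * rng[i].norm();
          if (gn < 0.0) gn = 0.0;
          g_noise[i] = gn;
          gd = gn;
        }
        if (stim_mean[i] > 0.0) {
          if (t >= stim_on[i] && t < stim_off[i]) {
            double gs = stim_mean[i] + (g_stim[i] - stim_mean[i]) * a_ou;
            if (stim_sd[i] > 0.0) gs += stim_sd[i] * b_ou * rng[i].norm();
            if (gs < 0.0) gs = 0.0;
            g_stim[i] = gs;
            gd += gs;
          } else {
            g_stim[i] = stim_mean[i]; // re-arm for window start
          }
        }
        g_drive[i] = gd;
      }
    }

    // cells: gates, voltage, spike detection
    for (int i = 0; i < ncell; ++i) {
      double v = V[i];
      const double vt = pVt[i];
      double am = 1.28 * xexprel(-(v - vt - 13.0) / 4.0);
      double bm = 1.40 * xexprel((v - vt - 40.0) / 5.0);
      double ah = 0.128 * fexp(-(v - vt - 17.0) / 18.0);
      double bh = 4.0 / (1.0 + fexp(-(v - vt - 40.0) / 5.0));
      double an = 0.16 * xexprel(-(v - vt - 15.0) / 5.0);
      double bn = 0.5 * fexp(-(v - vt - 10.0) / 40.0);
      double tot, inf;
      tot = am + bm; inf = am / tot;
      m[i] = inf + (m[i] - inf) * fexp(-tot * dt);
      tot = ah + bh; inf = ah / tot;
      h[i] = inf + (h[i] - inf) * fexp(-tot * dt);
      tot = an + bn; inf = an / tot;
      n[i] = inf + (n[i] - inf) * fexp(-tot * dt);
      double e20 = fexp((v + 35.0) / 20.0);
      double pin = e20 * e20 / (e20 * e20 + 1.0);
      double taup = pTaum[i] / (3.3 * e20 + 1.0 / e20);
      p[i] = pin + (p[i] - pin) * fexp(-dt / taup);

      const double gNa = pGna[i] * m[i] * m[i] * m[i] * h[i];
      const double n2 = n[i] * n[i];
      const double gKd = pGkd[i] * n2 * n2;
      const double gM = pGm[i] * p[i];
      double gn_block = 0.0;
      if (acc_nmda[i] > 0.0)
        gn_block = acc_nmda[i] / (1.0 + mg * fexp(-0.062 * v) / 3.57);
      const double ge = acc_e[i] + g_drive[i];
      const double g_tot = pGl[i] + gNa + gKd + gM + ge + gn_block + acc_i[i];
      const double A = pGl[i] * pEl[i] + gNa * pEna[i] + (gKd + gM) * pEk[i] +
        acc_iE[i];
      const double v_inf = A / g_tot;
      const double v_new = v_inf + (v - v_inf) * fexp(-g_tot * dt / pC[i]);
      if (!std::isfinite(v_new))
        stop("simulation diverged at cell %d, t = %.3f ms", i + 1, t_ms);
      if (v < 0.0 && v_new >= 0.0 && (t_ms - last_spike[i]) >= lockout_ms) {
        last_spike[i] = t_ms;
        spike_cell.push_back(i + 1);
        spike_time.push_back(t_ms);
        for (int k2 = adj_offset[i]; k2 < adj_offset[i + 1]; ++k2)
          ring[(t + syn_delay[k2]) % ring_n].push_back(k2);
      }
      V[i] = v_new;
    }

    if (nsamp > 0 && t % record_stride == 0 && samp < nsamp) {
      for (int j = 0; j < nrec; ++j) vrec(samp, j) = V[record_cells[j]];
      vrec_t[samp] = t_ms;
      ++samp;
    }
  }

  return List::create(
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_time),
    _["delivered"] = delivered,
    _["v_time"] = vrec_t,
    _["v"] = vrec,
    _["final_V"] = wrap(V));
}
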