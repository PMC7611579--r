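// Single-compartment place-cell surrogate: leaky resonant membrane
// (leak + slow negative-feedback conductance), GHK AMPAR/NMDAR synapses
// with Mg block, threshold-reset spiking with adaptation, and in-loop
// Bernoulli sampling of presynaptic events from a zero-order-held rate
// grid. Exponential Euler on the leak and the slow variable; synaptic and
// adaptation currents explicit. Units: mV, nA, uS, nF, ms.
#include <Rcpp.h>
using namespace Rcpp;

static inline double ghk_flux_c(double v_mV, double z, double ci, double co,
                                double rtf_mV, double F_const) {
  double u = z * v_mV / rtf_mV;
  double emu = std::exp(-u);
  double num = ci - co * emu;
  if (std::fabs(u) < 1e-4) {
    // u / (1 - exp(-u)) = 1 + u/2 + u^2/12 + O(u^4)
    return z * F_const * (1.0 + u / 2.0 + u * u / 12.0) * num;
  }
  return z * F_const * u * num / (1.0 - emu);
}

// [[Rcpp::export]]
List sim_core(int n_steps, double dt, NumericVector i_inj,
              NumericMatrix rate_khz, double grid_dt,
              NumericVector col_weight, IntegerVector col_mult,
              NumericVector ev_time, NumericVector ev_weight,
              List syn, List memb,
              bool spiking, bool return_trace, bool sample) {
  // membrane
  const double gL = memb["gL"], gw = memb["gw"], tau_w = memb["tau_w"];
  const double Cm = memb["C"], EL = memb["EL"];
  const double theta = memb["theta"], reset = memb["reset"];
  const double refrac = memb["refrac"];
  const double b_adapt = memb["b_adapt"], tau_adapt = memb["tau_adapt"];
  const double v0 = memb["v0"];
  // synapse
  const double p_ampa = syn["p_ampa"], p_nmda = syn["p_nmda"];
  const double tau_r_a = syn["tau_r_a"], tau_d_a = syn["tau_d_a"];
  const double tau_r_n = syn["tau_r_n"], tau_d_n = syn["tau_d_n"];
  const double norm_a = syn["norm_a"], norm_n = syn["norm_n"];
  const NumericVector z = syn["z"], ci = syn["ci"], co = syn["co"];
  const NumericVector perm_a = syn["perm_a"], perm_n = syn["perm_n"];
  const double rtf = syn["rtf"], F_const = syn["F_const"];
  const double mg_out = syn["mg_out"];

  const double dec_r_a = std::exp(-dt / tau_r_a);
  const double dec_d_a = std::exp(-dt / tau_d_a);
  const double dec_r_n = std::exp(-dt / tau_r_n);
  const double dec_d_n = std::exp(-dt / tau_d_n);
  const double dec_w   = std::exp(-dt * gL / Cm);   // exp-Euler leak factor
  const double dec_sw  = std::exp(-dt / tau_w);
  const double dec_ad  = std::exp(-dt / tau_adapt);

  const int n_cols = rate_khz.ncol();
  const int n_grid = rate_khz.nrow();
  const bool inj_scalar = (i_inj.size() == 1);

  double v = v0, w = 0.0, i_ad = 0.0;
  double xr_a = 0.0, xd_a = 0.0, xr_n = 0.0, xd_n = 0.0;
  double refrac_until = -1.0;
  long n_events = 0;
  int ev_ptr = 0;
  const int n_ev = ev_time.size();

  std::vector<double> spikes;
  NumericVector trace(return_trace ? n_steps : 0);
  // stereotyped 1 ms spike waveform pasted into the returned trace
  const int wave_n = std::max(1, (int)std::round(1.0 / dt));
  std::vector<double> wave(wave_n);
  {
    int up = std::max(1, (int)std::round(0.25 / dt));
    for (int i = 0; i < wave_n; ++i) {
      if (i < up) wave[i] = theta + (35.0 - theta) * (i + 1.0) / up;
      else wave[i] = 35.0 + (reset - 35.0) * (i - up + 1.0) / (wave_n - up);
    }
  }
  int wave_pos = wave_n;  // past the end = no waveform being pasted

  // Presynaptic Bernoulli sampling, vectorised per rate-grid window: for
  // each (window, synapse column) the number of events over the
  // steps-in-window iid Bernoulli(p) trials is Binomial(m, p), and the
  // event steps are uniform without replacement - distributionally
  // identical to a per-step draw, at a fraction of the RNG calls.
  std::vector<double> sampled_add;
  if (sample && n_cols > 0) {
    sampled_add.assign(n_steps, 0.0);
    int spg = std::max(1, (int)std::round(grid_dt / dt));
    std::vector<char> used(spg);
    for (int g0 = 0, gi = 0; g0 < n_steps; g0 += spg, ++gi) {
      int m = std::min(spg, n_steps - g0);
      int gidx = gi < n_grid ? gi : n_grid - 1;
      for (int c = 0; c < n_cols; ++c) {
        double p = rate_khz(gidx, c) * dt;
        if (p <= 0.0) continue;
        int total = col_mult[c];
        int k = (int)R::rbinom((double)(m * total), p > 1.0 ? 1.0 : p);
        if (k == 0) continue;
        n_events += k;
        if (total == 1) {  // distinct steps within the window
          std::fill(used.begin(), used.begin() + m, 0);
          for (int e = 0; e < k; ++e) {
            int off;
            do { off = (int)(unif_rand() * m); if (off >= m) off = m - 1; }
            while (used[off]);
            used[off] = 1;
            sampled_add[g0 + off] += col_weight[c];
          }
        } else {
          // many equivalent synapses per column: events occupy distinct
          // (synapse, step) pairs; different synapses may share a step
          long npair = (long)m * total;
          std::vector<long> chosen;
          chosen.reserve(k);
          for (int e = 0; e < k; ++e) {
            long pair;
            bool dup;
            do {
              pair = (long)(unif_rand() * npair);
              if (pair >= npair) pair = npair - 1;
              dup = false;
              for (size_t q = 0; q < chosen.size(); ++q)
                if (chosen[q] == pair) { dup = true; break; }
            } while (dup);
            chosen.push_back(pair);
            sampled_add[g0 + (int)(pair % m)] += col_weight[c];
          }
        }
      }
    }
  }

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // presynaptic events: listed events first
    double add = 0.0;
    while (ev_ptr < n_ev && ev_time[ev_ptr] <= t + 1e-9) {
      add += ev_weight[ev_ptr];
      ++ev_ptr;
      ++n_events;
    }
    if (!sampled_add.empty()) add += sampled_add[step];

    // kinetic state decay + event increments
    xr_a = xr_a * dec_r_a + add;
    xd_a = xd_a * dec_d_a + add;
    xr_n = xr_n * dec_r_n + add;
    xd_n = xd_n * dec_d_n + add;
    double s_a = norm_a * (xd_a - xr_a);
    double s_n = norm_n * (xd_n - xr_n);

    // synaptic current (GHK sign convention: inward negative)
    double i_syn = 0.0;
    if (p_ampa > 0.0 || p_nmda > 0.0) {
      double fl[3];
      for (int k = 0; k < 3; ++k)
        fl[k] = ghk_flux_c(v, z[k], ci[k], co[k], rtf, F_const);
      double i_a = 0.0, i_n = 0.0;
      for (int k = 0; k < 3; ++k) {
        i_a += perm_a[k] * fl[k];
        i_n += perm_n[k] * fl[k];
      }
      double blk = 1.0 / (1.0 + mg_out * std::exp(-0.062 * v) / 3.57);
      i_syn = p_ampa * s_a * i_a + p_nmda * s_n * blk * i_n;
    }

    // slow resonant variable (exp-Euler toward V - EL)
    w = w * dec_sw + (v - EL) * (1.0 - dec_sw);
    i_ad *= dec_ad;

    double inj = inj_scalar ? i_inj[0] : i_inj[step];
    if (t < refrac_until) {
      v = reset;
    } else {
      double v_inf = EL + (-gw * w - i_syn - i_ad + inj) / gL;
      v = v_inf + (v - v_inf) * dec_w;
      if (spiking && v >= theta) {
        spikes.push_back(t);
        v = reset;
        i_ad += b_adapt;
        refrac_until = t + refrac;
        wave_pos = 0;
      }
    }
    if (!std::isfinite(v) || std::fabs(v) > 200.0) {
      stop("integration blew up at step %d (t = %.3f ms)", step, t);
    }
    if (return_trace) {
      if (wave_pos < wave_n) {
        trace[step] = wave[wave_pos];
        ++wave_pos;
      } else {
        trace[step] = v;
      }
    }
  }

  List out = List::create(
    _["spikes_ms"] = NumericVector(spikes.begin(), spikes.end()),
    _["n_presyn_events"] = (double)n_events);
  if (return_trace) out["v"] = trace;
  return out;
}
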