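// Core integrator: passive ball-and-stick cable (backward Euler, Thomas
// solver), spine compartments condensed onto their shaft node, triple-
// exponential AMPA/NMDA conductances with Mg block, stereotyped somatic AP
// voltage command (threshold-triggered or scheduled), ideal somatic voltage
// clamp, and the sparseness-gradient plasticity rule integrated per step.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double grad_skew(double uh, double ud, double s2, double g6) {
  double a = std::fabs(uh);
  double u6 = uh * uh;
  u6 = u6 * u6 * u6;
  return 0.25 * (ud * uh - 2.0 * s2) * a * a * a / (u6 + g6);
}

static inline double grad_kurt(double uh, double ud, double s2, double g8) {
  double u2 = uh * uh;
  double u5 = u2 * u2 * uh;
  double u8 = u2 * u2;
  u8 = u8 * u8;
  return (2.0 / 3.0) * (ud * uh - 1.5 * s2) * u5 / (u8 + g8);
}

struct Receptor {
  double lam, norm, e_rev;
  double dec_r, dec_d1, dec_d2;
  double x_r, x_d1, x_d2;
  void decay() { x_r *= dec_r; x_d1 *= dec_d1; x_d2 *= dec_d2; }
  void spike() { x_r += 1.0; x_d1 += 1.0; x_d2 += 1.0; }
  double ghat() const {
    return norm * (lam * x_d1 + (1.0 - lam) * x_d2 - x_r);
  }
};

struct Syn {
  int node;
  Receptor rec[2];            // 0 = AMPA, 1 = NMDA
  double w[2], w0[2];
  double mg_ratio, mg_alpha;  // mg_out / beta, alpha
  double g_neck, c_head, g_leak_head;
  double u_head, u_bar, sigma2;
  std::vector<double> pre;
  size_t pre_idx;
  double D, alf, gsyn[2], ghat_eff[2];  // per-step scratch (gsyn in nS)
};

// [[Rcpp::export]]
List cpp_simulate(List neuron, List synapses, List plasticity, List events,
                  double duration, List record) {
  // ---- cable geometry ----
  const int ncomp = as<int>(neuron["n_comp"]);
  const double L = as<double>(neuron["total_length"]);
  const double diam = as<double>(neuron["diam"]);
  const double ri = as<double>(neuron["ri"]);       // Ohm cm
  const double rm = as<double>(neuron["rm"]);       // Ohm cm^2
  const double cm = as<double>(neuron["cm"]);       // uF/cm^2
  const double e_rest = as<double>(neuron["e_rest"]);
  const double soma_diam = as<double>(neuron["soma_diam"]);
  const double dt = as<double>(neuron["dt"]);

  const bool spiking = as<bool>(neuron["spiking"]);
  const double v_th = as<double>(neuron["v_th"]);
  const double th_inc = as<double>(neuron["th_adapt_inc"]);   // mV per spike
  const double th_tau = as<double>(neuron["th_adapt_tau"]);   // ms
  const double refrac = as<double>(neuron["refractory"]);
  const double ap_amp = as<double>(neuron["ap_amp"]);
  const double ap_tau_r = as<double>(neuron["ap_tau_r"]);
  const double ap_tau_d = as<double>(neuron["ap_tau_d"]);
  const double ap_window = as<double>(neuron["ap_window"]);
  const double ap_gmax = as<double>(neuron["ap_gmax"]);   // nS
  const double adp_amp = as<double>(neuron["adp_amp"]);   // pA
  const double adp_tau = as<double>(neuron["adp_tau"]);   // ms

  const int nn = ncomp + 1;                 // node 0 = soma
  const double dx = L / ncomp;
  std::vector<double> Cn(nn), gL(nn), gax(ncomp);
  {
    const double a_soma = M_PI * soma_diam * soma_diam;   // sphere, um^2
    const double a_comp = M_PI * diam * dx;
    Cn[0] = 0.01 * cm * a_soma;             // pF
    gL[0] = 10.0 * a_soma / rm;             // nS
    for (int i = 1; i < nn; ++i) {
      Cn[i] = 0.01 * cm * a_comp;
      gL[i] = 10.0 * a_comp / rm;
    }
    const double cross = M_PI * diam * diam / 4.0;        // um^2
    const double r_full = ri * 1e4 * dx / cross;          // Ohm
    gax[0] = 1e9 / (ri * 1e4 * (dx / 2.0) / cross);       // soma -> comp 1
    for (int i = 1; i < ncomp; ++i) gax[i] = 1e9 / r_full;
  }

  // ---- synapses ----
  const int nsyn = synapses.size();
  std::vector<Syn> syn(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    List sl = synapses[s];
    Syn &S = syn[s];
    S.node = as<int>(sl["node"]);
    NumericVector ka = sl["kin_ampa"], kn = sl["kin_nmda"];
    // kinetics vectors: tau_r, tau_d1, tau_d2, lam, norm, e_rev
    for (int r = 0; r < 2; ++r) {
      NumericVector k = (r == 0) ? ka : kn;
      S.rec[r].dec_r = std::exp(-dt / k[0]);
      S.rec[r].dec_d1 = std::exp(-dt / k[1]);
      S.rec[r].dec_d2 = std::exp(-dt / k[2]);
      S.rec[r].lam = k[3];
      S.rec[r].norm = k[4];
      S.rec[r].e_rev = k[5];
      S.rec[r].x_r = S.rec[r].x_d1 = S.rec[r].x_d2 = 0.0;
    }
    S.w[0] = S.w0[0] = as<double>(sl["w_ampa"]);
    S.w[1] = S.w0[1] = as<double>(sl["w_nmda"]);
    NumericVector mg = sl["mg"];
    S.mg_ratio = mg[0] / mg[2];
    S.mg_alpha = mg[1];
    S.g_neck = as<double>(sl["g_neck"]);
    S.c_head = as<double>(sl["c_head"]);
    S.g_leak_head = as<double>(sl["g_leak_head"]);
    NumericVector pt = sl["pre_times"];
    S.pre.assign(pt.begin(), pt.end());
    S.pre_idx = 0;
    S.u_head = e_rest;
    S.sigma2 = as<double>(sl["sigma2_scale"]);
  }

  // ---- plasticity ----
  const bool plast_on = as<bool>(plasticity["enabled"]);
  const double eta_ms = as<double>(plasticity["eta"]) * 1000.0;
  const double gamma = as<double>(plasticity["gamma"]);
  const double sigma2 = as<double>(plasticity["sigma2"]);
  const double tau_ubar = as<double>(plasticity["tau_ubar_ms"]);
  const int measure = as<int>(plasticity["measure"]);   // 0 skew, 1 kurt
  const int mode = as<int>(plasticity["mode"]);         // 0 mult, 1 additive
  const double c_eff = as<double>(plasticity["c_eff"]);
  const double u_bar0 = as<double>(plasticity["u_bar0"]);
  const double g6 = std::pow(gamma, 6), g8 = std::pow(gamma, 8);
  const double ubar_dec = std::exp(-dt / tau_ubar);
  for (int s = 0; s < nsyn; ++s) {
    syn[s].u_bar = u_bar0;
    syn[s].sigma2 *= sigma2;
  }

  // ---- events ----
  NumericMatrix inj = events["injections"];   // t0, dur, amp(pA)
  NumericVector ap_sched = events["ap_times"];
  const bool clamp_on = as<bool>(events["clamp_active"]);
  const double clamp_v = as<double>(events["clamp_v"]);

  std::vector<double> ap_starts(ap_sched.begin(), ap_sched.end());
  size_t ap_base = 0;   // first AP still inside its window
  size_t ap_adp = 0;    // next scheduled AP whose ADP has not started yet
  double adp_state = 0; // summed after-depolarizing somatic current (pA)
  double th_state = 0;  // adaptive increment of the spike threshold (mV)
  const double adp_dec = std::exp(-dt / adp_tau);
  const double th_dec = std::exp(-dt / th_tau);
  double last_trig = -1e18;
  std::vector<double> trig_spikes;
  const double ap_xpk = std::log(ap_tau_d / ap_tau_r) * ap_tau_r * ap_tau_d /
                        (ap_tau_d - ap_tau_r);
  const double ap_speak = std::exp(-ap_xpk / ap_tau_d) -
                          std::exp(-ap_xpk / ap_tau_r);

  // ---- recording ----
  const double rec_dt = as<double>(record["rec_dt"]);
  IntegerVector rec_nodes = record["nodes"];
  const bool rec_syn = as<bool>(record["syn_traces"]);
  const double w_dt = as<double>(record["weight_dt"]);
  const int nsteps = (int)std::lround(duration / dt);
  const int rec_stride = std::max(1, (int)std::lround(rec_dt / dt));
  const int w_stride = std::max(1, (int)std::lround(w_dt / dt));
  const int nrec = nsteps / rec_stride + 1;
  const int nwrec = nsteps / w_stride + 1;

  NumericVector rtimes(nrec);
  NumericMatrix V(nrec, rec_nodes.size());
  NumericMatrix Hu, Hud, Hub;
  if (rec_syn) {
    Hu = NumericMatrix(nrec, nsyn);
    Hud = NumericMatrix(nrec, nsyn);
    Hub = NumericMatrix(nrec, nsyn);
  }
  NumericVector wtimes(nwrec);
  NumericMatrix Wa(nwrec, nsyn), Wn(nwrec, nsyn);

  // ---- state ----
  std::vector<double> u(nn, e_rest), diag(nn), rhs(nn), cp(nn), dp(nn);
  size_t inj_idx = 0;

  auto record_state = [&](int k, double t) {
    rtimes[k] = t;
    for (int j = 0; j < rec_nodes.size(); ++j) V(k, j) = u[rec_nodes[j]];
    if (rec_syn) {
      for (int s = 0; s < nsyn; ++s) {
        Hu(k, s) = syn[s].u_head;
        Hub(k, s) = syn[s].u_bar;
      }
    }
  };
  record_state(0, 0.0);
  if (rec_syn) for (int s = 0; s < nsyn; ++s) Hud(0, s) = 0.0;
  wtimes[0] = 0.0;
  for (int s = 0; s < nsyn; ++s) { Wa(0, s) = syn[s].w[0]; Wn(0, s) = syn[s].w[1]; }

  int ri_rec = 1, wi_rec = 1;
  bool blew_up = false;

  for (int k = 1; k <= nsteps; ++k) {
    const double t_next = k * dt;

    // synapse conductances and spine condensation terms
    for (int s = 0; s < nsyn; ++s) {
      Syn &S = syn[s];
      for (int r = 0; r < 2; ++r) S.rec[r].decay();
      while (S.pre_idx < S.pre.size() && S.pre[S.pre_idx] <= t_next + 1e-9) {
        S.rec[0].spike();
        S.rec[1].spike();
        ++S.pre_idx;
      }
      const double mgfac = 1.0 / (1.0 + S.mg_ratio *
                                  std::exp(-S.mg_alpha * S.u_head));
      S.ghat_eff[0] = S.rec[0].ghat();
      S.ghat_eff[1] = S.rec[1].ghat() * mgfac;
      S.gsyn[0] = S.w[0] * 1e-3 * S.ghat_eff[0];
      S.gsyn[1] = S.w[1] * 1e-3 * S.ghat_eff[1];
      const double gtot = S.gsyn[0] + S.gsyn[1];
      S.D = S.c_head / dt + S.g_leak_head + S.g_neck + gtot;
      S.alf = S.c_head / dt * S.u_head + S.g_leak_head * e_rest +
              S.gsyn[0] * S.rec[0].e_rev + S.gsyn[1] * S.rec[1].e_rev;
    }

    // assemble tridiagonal system
    for (int i = 0; i < nn; ++i) {
      diag[i] = Cn[i] / dt + gL[i];
      rhs[i] = Cn[i] / dt * u[i] + gL[i] * e_rest;
    }
    for (int i = 0; i < ncomp; ++i) { diag[i] += gax[i]; diag[i + 1] += gax[i]; }
    for (int s = 0; s < nsyn; ++s) {
      Syn &S = syn[s];
      diag[S.node] += S.g_neck * (1.0 - S.g_neck / S.D);
      rhs[S.node] += S.g_neck * S.alf / S.D;
    }
    // injections are sorted by onset with equal durations, so a moving
    // window over the rows suffices
    // eliciting pulses are ineffective while the spike mechanism is
    // refractory (without this, a pulse landing just after an AP would
    // depolarize the passive soma without bound instead of firing it)
    const double last_ap = (ap_adp > 0) ? ap_starts[ap_adp - 1] : -1e18;
    bool inj_active = false;
    while (inj_idx < (size_t)inj.nrow() &&
           t_next >= inj(inj_idx, 0) + inj(inj_idx, 1)) ++inj_idx;
    if (t_next - last_ap >= refrac || t_next <= last_ap) {
      for (size_t j = inj_idx; j < (size_t)inj.nrow(); ++j) {
        if (inj(j, 0) > t_next) break;
        if (t_next < inj(j, 0) + inj(j, 1)) {
          rhs[0] += inj(j, 2);
          inj_active = true;
        }
      }
    }

    // after-depolarizing current of recent APs (keeps the soma depolarized
    // between high-frequency spikes; the forced fast waveform alone would
    // drain the dendrite back to rest each cycle)
    adp_state *= adp_dec;
    th_state *= th_dec;
    while (ap_adp < ap_starts.size() && ap_starts[ap_adp] <= t_next) {
      adp_state += adp_amp;
      th_state += th_inc;
      ++ap_adp;
    }
    rhs[0] += adp_state;

    // somatic AP drive: the stereotyped spike waveform is imposed through a
    // strong conductance toward the command voltage (dynamic-clamp style),
    // so the waveform dominates during the spike but hands back smoothly to
    // the membrane equation as it decays -- no release discontinuity, and
    // depolarization can accumulate between high-frequency spikes
    bool forced = false;   // exact forcing is used only by the voltage clamp
    double v_cmd = 0.0;
    if (clamp_on) {
      forced = true;
      v_cmd = clamp_v;
    } else {
      while (ap_base < ap_starts.size() &&
             t_next - ap_starts[ap_base] >= ap_window) ++ap_base;
      double ssum = 0.0;
      for (size_t a = ap_base; a < ap_starts.size(); ++a) {
        const double x = t_next - ap_starts[a];
        if (x < 0.0) break;
        ssum += std::exp(-x / ap_tau_d) - std::exp(-x / ap_tau_r);
      }
      if (ssum > 0.0) {
        const double shape = ssum / ap_speak;
        // conductance ~ shape^2: commands the spike peak strongly but dies
        // off faster than the waveform, so the late repolarization hands
        // over to the membrane's own relaxation instead of draining it
        const double g_ap = ap_gmax * shape * shape;
        diag[0] += g_ap;
        rhs[0] += g_ap * (e_rest + ap_amp * shape);
      }
    }

    // Thomas solve (sub/super diagonals are -gax)
    if (forced) {
      // row 0: u[0] = v_cmd
      cp[0] = 0.0;
      dp[0] = v_cmd;
    } else {
      cp[0] = -gax[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
    }
    for (int i = 1; i < nn; ++i) {
      const double a = -gax[i - 1];
      const double c = (i < ncomp) ? -gax[i] : 0.0;
      const double m = diag[i] - a * cp[i - 1];
      cp[i] = c / m;
      dp[i] = (rhs[i] - a * dp[i - 1]) / m;
    }
    u[nn - 1] = dp[nn - 1];
    for (int i = nn - 2; i >= 0; --i) u[i] = dp[i] - cp[i] * u[i + 1];

    if (std::fabs(u[0]) > 200.0 || std::fabs(u[nn - 1]) > 200.0) {
      blew_up = true;
      break;
    }

    // spine heads, plasticity, running average
    for (int s = 0; s < nsyn; ++s) {
      Syn &S = syn[s];
      const double uh_new = (S.alf + S.g_neck * u[S.node]) / S.D;
      const double udot = (uh_new - S.u_head) / dt;
      if (plast_on) {
        // The gradient is sharply peaked in u_hat (width ~ gamma), so a
        // fast voltage sweep (bAP rise/decay) crosses its support within a
        // few steps. Integrate the gradient along the (linear-in-t) voltage
        // path with midpoint substeps fine enough to resolve the peak;
        // endpoint or single-midpoint sampling biases the rise/decay
        // balance and with it the STDP window.
        const double du = uh_new - S.u_head;
        int m = (int)std::ceil(std::fabs(du) / 0.25);
        if (m < 1) m = 1;
        if (m > 64) m = 64;
        double acc[2] = {0.0, 0.0};
        for (int j = 0; j < m; ++j) {
          const double uj = S.u_head + du * (j + 0.5) / m;
          const double xj = uj - S.u_bar;
          const double g = (measure == 0)
            ? grad_skew(xj, udot, S.sigma2, g6)
            : grad_kurt(xj, udot, S.sigma2, g8);
          // Mg unblock tracks the substep voltage: the one-step lag used in
          // the implicit cable solve would skew the rise/decay balance here
          const double mgj = 1.0 / (1.0 + S.mg_ratio *
                                    std::exp(-S.mg_alpha * uj));
          acc[0] += g * (S.rec[0].e_rev - uj);
          acc[1] += g * mgj * (S.rec[1].e_rev - uj);
        }
        const double gh_raw[2] = {S.rec[0].ghat(), S.rec[1].ghat()};
        for (int r = 0; r < 2; ++r) {
          const double w_drive = (mode == 1) ? S.w0[r] : S.w[r];
          if (w_drive <= 0.0) continue;
          const double i_g = w_drive * 1e-3 * gh_raw[r] * acc[r] / m;
          S.w[r] += eta_ms * (i_g / c_eff) * dt;
          if (S.w[r] < 0.0) S.w[r] = 0.0;
        }
      }
      S.u_head = uh_new;
      S.u_bar = uh_new + (S.u_bar - uh_new) * ubar_dec;
      if (rec_syn && k % rec_stride == 0) Hud(ri_rec, s) = udot;
    }

    // threshold-triggered somatic AP (takes effect next step); the
    // refractory period must outlast the suprathreshold part of the AP
    // command tail, or the waveform would re-trigger itself
    (void)inj_active;
    if (spiking && !forced && u[0] >= v_th + th_state &&
        t_next - last_trig >= refrac) {
      ap_starts.push_back(t_next);
      last_trig = t_next;
      trig_spikes.push_back(t_next);
    }

    if (k % rec_stride == 0) { record_state(ri_rec, t_next); ++ri_rec; }
    if (k % w_stride == 0) {
      wtimes[wi_rec] = t_next;
      for (int s = 0; s < nsyn; ++s) {
        Wa(wi_rec, s) = syn[s].w[0];
        Wn(wi_rec, s) = syn[s].w[1];
      }
      ++wi_rec;
    }
    if (k % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  if (blew_up) stop("integration failure: |u| exceeded 200 mV");

  NumericVector w_ampa_final(nsyn), w_nmda_final(nsyn), ubar_final(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    w_ampa_final[s] = syn[s].w[0];
    w_nmda_final[s] = syn[s].w[1];
    ubar_final[s] = syn[s].u_bar;
  }

  List out = List::create(
    _["times"] = rtimes, _["v"] = V,
    _["w_times"] = wtimes, _["w_ampa"] = Wa, _["w_nmda"] = Wn,
    _["w_ampa_final"] = w_ampa_final, _["w_nmda_final"] = w_nmda_final,
    _["u_bar_final"] = ubar_final,
    _["spikes"] = NumericVector(trig_spikes.begin(), trig_spikes.end()));
  if (rec_syn) {
    out["head_u"] = Hu;
    out["head_udot"] = Hud;
    out["head_ubar"] = Hub;
  }
  return out;
}
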