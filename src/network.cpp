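// Two-stage LIF network: two sensory populations feeding two integration
// ("decision") populations that compete through a shared inhibitory pool,
// with integration-to-sensory feedback. NMDA conductances of selected
// integration neurons are scaled down to emulate local receptor blockade.
//
// Populations (indices): 0 = S1 (sensory, RF stimulus), 1 = S2 (sensory,
// away stimulus), 2 = D1 ("attend RF" integration), 3 = D2 ("attend away"
// integration), 4 = shared inhibitory pool.
//
// Dimensionless conductances (units of the leak conductance); voltages in
// mV, time in ms. NMDA gating follows the standard two-variable scheme with
// saturation and the Mg2+ voltage dependence 1/(1 + Mg/3.57 exp(-0.062 V)).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(List cfg, bool keep_spikes) {
  const int nS = as<int>(cfg["n_sensory"]);
  const int nD = as<int>(cfg["n_decision"]);
  const int nI = as<int>(cfg["n_inhibitory"]);
  const double dt = as<double>(cfg["dt"]);
  const double duration = as<double>(cfg["duration"]);
  const double t_stim_on = as<double>(cfg["t_stim_on"]);
  if (dt > 0.1) stop("dt must be <= 0.1 ms");

  const int npop = 5;
  const int sizes[5] = {nS, nS, nD, nD, nI};
  int offset[5], N = 0;
  for (int p = 0; p < npop; ++p) { offset[p] = N; N += sizes[p]; }

  // neuron parameters (E cells; inhibitory pool has its own tau/refrac)
  const double EL = -70.0, Vth = -50.0, Vreset = -55.0;
  const double tau_e = as<double>(cfg["tau_m_e"]);   // ms
  const double tau_i = as<double>(cfg["tau_m_i"]);
  const double ref_e = as<double>(cfg["refrac_e"]);  // ms
  const double ref_i = as<double>(cfg["refrac_i"]);

  const double E_ampa = 0.0, E_nmda = 0.0, E_gaba = -70.0;
  const double tau_ampa = 2.0, tau_gaba = 5.0;
  const double tau_nmda = 100.0, tau_x = 2.0, alpha_nmda = 0.5;

  // connection conductances, normalised per source neuron inside the code
  NumericMatrix w_ampa = as<NumericMatrix>(cfg["w_ampa"]);   // 5x5 src x dst
  NumericMatrix w_nmda = as<NumericMatrix>(cfg["w_nmda"]);
  NumericMatrix w_gaba = as<NumericMatrix>(cfg["w_gaba"]);

  // external drive (mV equivalents) and noise
  const double drive_bg = as<double>(cfg["drive_bg"]);
  const double drive_bg_i = as<double>(cfg["drive_bg_i"]);
  const double drive_stim = as<double>(cfg["drive_stim"]);
  const double stim_sigma = as<double>(cfg["stim_sigma"]);   // OU fraction
  const double stim_tau = as<double>(cfg["stim_tau"]);       // ms
  const double noise_sd = as<double>(cfg["noise_sd"]);       // mV/sqrt(ms)
  const double drive_het_sd = as<double>(cfg["drive_het_sd"]); // mV, static

  // per-neuron NMDA scaling of incoming conductances (blockade emulation)
  NumericVector nmda_scale = as<NumericVector>(cfg["nmda_scale"]); // len N

  std::vector<double> V(N), refr(N, 0.0), s_ampa(N, 0.0), s_nmda(N, 0.0),
      x_nmda(N, 0.0), s_gaba(N, 0.0);
  std::vector<int> pop(N), nspk(N, 0);
  for (int p = 0; p < npop; ++p)
    for (int i = offset[p]; i < offset[p] + sizes[p]; ++i) pop[i] = p;
  for (int i = 0; i < N; ++i) V[i] = EL + R::runif(0.0, 5.0);
  // static per-neuron excitability heterogeneity (excitatory cells)
  std::vector<double> het(N, 0.0);
  for (int i = 0; i < N; ++i)
    if (pop[i] != 4) het[i] = drive_het_sd * R::norm_rand();

  const int nsteps = (int)(duration / dt + 0.5);
  const double mg = 1.0;
  double ou1 = 0.0, ou2 = 0.0;  // shared stimulus fluctuations per sensory pop

  std::vector<double> spk_t;
  std::vector<int> spk_i;
  const double rate_t0 = as<double>(cfg["rate_win_start"]);
  const double rate_t1 = as<double>(cfg["rate_win_end"]);
  std::vector<int> nspk_win(N, 0);

  const double ou_decay = std::exp(-dt / stim_tau);
  const double ou_sd = std::sqrt(1.0 - ou_decay * ou_decay);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // population-aggregated gating (uniform all-to-all connectivity)
    double A[5] = {0, 0, 0, 0, 0}, Nm[5] = {0, 0, 0, 0, 0},
           G[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < N; ++i) {
      A[pop[i]] += s_ampa[i];
      Nm[pop[i]] += s_nmda[i];
      G[pop[i]] += s_gaba[i];
    }
    for (int p = 0; p < npop; ++p) {
      A[p] /= sizes[p]; Nm[p] /= sizes[p]; G[p] /= sizes[p];
    }

    // stimulus fluctuation (independent OU per sensory population)
    ou1 = ou1 * ou_decay + ou_sd * R::norm_rand();
    ou2 = ou2 * ou_decay + ou_sd * R::norm_rand();
    const bool stim = t >= t_stim_on;

    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { refr[i] -= dt; }
      const int p = pop[i];
      double ga = 0, gn = 0, gg = 0;
      for (int q = 0; q < npop; ++q) {
        ga += w_ampa(q, p) * A[q];
        gn += w_nmda(q, p) * Nm[q];
        gg += w_gaba(q, p) * G[q];
      }
      gn *= nmda_scale[i];
      const double fmg = 1.0 / (1.0 + mg / 3.57 * std::exp(-0.062 * V[i]));
      double drive = ((p == 4) ? drive_bg_i : drive_bg) + het[i];
      if (stim) {
        if (p == 0) drive += drive_stim * (1.0 + stim_sigma * ou1);
        if (p == 1) drive += drive_stim * (1.0 + stim_sigma * ou2);
      }
      const double taum = (p == 4) ? tau_i : tau_e;
      double dV = (-(V[i] - EL) + drive
                   - ga * (V[i] - E_ampa)
                   - gn * fmg * (V[i] - E_nmda)
                   - gg * (V[i] - E_gaba)) / taum;
      if (refr[i] <= 0) {
        V[i] += dt * dV + noise_sd * std::sqrt(dt) * R::norm_rand();
        if (V[i] >= Vth) {
          V[i] = Vreset;
          refr[i] = (p == 4) ? ref_i : ref_e;
          nspk[i]++;
          if (t >= rate_t0 && t < rate_t1) nspk_win[i]++;
          if (keep_spikes) { spk_t.push_back(t); spk_i.push_back(i + 1); }
          if (p == 4) s_gaba[i] += 1.0;
          else { s_ampa[i] += 1.0; x_nmda[i] += 1.0; }
        }
      }
      // synaptic gating decay / NMDA saturation
      s_ampa[i] -= dt * s_ampa[i] / tau_ampa;
      s_gaba[i] -= dt * s_gaba[i] / tau_gaba;
      s_nmda[i] += dt * (-s_nmda[i] / tau_nmda +
                         alpha_nmda * x_nmda[i] * (1.0 - s_nmda[i]));
      x_nmda[i] -= dt * x_nmda[i] / tau_x;
    }
  }

  NumericVector rates(N), rates_win(N);
  IntegerVector popv(N);
  const double win_s = (rate_t1 - rate_t0) / 1000.0;
  for (int i = 0; i < N; ++i) {
    rates[i] = nspk[i] / (duration / 1000.0);
    rates_win[i] = nspk_win[i] / win_s;
    popv[i] = pop[i] + 1;
  }
  List out = List::create(_["rates"] = rates, _["rates_win"] = rates_win,
                          _["population"] = popv,
                          _["nmda_scale"] = nmda_scale);
  if (keep_spikes)
    out["spikes"] = DataFrame::create(_["neuron"] = wrap(spk_i),
                                      _["t_ms"] = wrap(spk_t));
  return out;
}
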