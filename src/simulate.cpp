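#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler simulation of the pyramidal/interneuron network with
// conductance synapses.  Connectivity is the bipartite scheme:
// each pyramidal cell couples to exactly one interneuron and the inhibitory
// matrix is the transpose, so every pyramidal cell attached to interneuron j
// sees the same inhibitory conductance trace and a single scalar per
// interneuron suffices for each synapse type.
//
// All quantities are SI.  The membrane update uses the previous-step
// voltage (explicit Euler); threshold is tested after the update; synaptic
// conductances decay exactly by exp(-dt/tau) between spikes and are
// incremented by the synaptic weight at presynaptic spikes (effective from
// the next step).  Membrane noise (default): per-step increment
// sigma_n*sqrt(2*dt/tau_m)*eta with standard-normal eta, i.e. an
// Ornstein-Uhlenbeck calibration in which sigma_n is the stationary
// standard deviation of the subthreshold voltage noise, independent of dt.
// The alternative timestep-bound mode adds (sigma_n/tau_m)*eta*dt, which
// ties the effective noise to the timestep.

// [[Rcpp::export]]
List simulate_lif_cpp(int n_pyr, int n_int, IntegerVector pyr2int,
                      double wE, double wI,
                      double tau_m_E, double Cm_E, double E0_E, double Vth_E,
                      double Vr_E, double sigma_E,
                      double tau_m_I, double Cm_I, double E0_I, double Vth_I,
                      double Vr_I, double sigma_I,
                      double E_rev_E, double E_rev_I, double tau_E, double tau_I,
                      double I0I, double Itheta, double f_theta,
                      NumericVector IE, NumericVector xc, double sigma_field,
                      double x0, double v, double lateral,
                      double pert_I_pyr, double pert_I_int,
                      double pert_on, double pert_off, bool pert_reset,
                      double T, double dt,
                      IntegerVector record_pyr, IntegerVector record_int,
                      int record_every, bool sqrt_dt_noise) {
  const int n_steps = (int)std::lround(T / dt);
  const double om_theta = 2.0 * M_PI * f_theta;
  const double decE = std::exp(-dt / tau_E);
  const double decI = std::exp(-dt / tau_I);
  const double noise_scale_E = sqrt_dt_noise ? sigma_E * std::sqrt(2.0 * dt / tau_m_E)
                                             : sigma_E * dt / tau_m_E;
  const double noise_scale_I = sqrt_dt_noise ? sigma_I * std::sqrt(2.0 * dt / tau_m_I)
                                             : sigma_I * dt / tau_m_I;

  std::vector<double> V_E(n_pyr, E0_E), V_I(n_int, E0_I);
  std::vector<double> gE(n_int, 0.0);  // excitatory conductance onto interneurons
  std::vector<double> gI(n_int, 0.0);  // inhibitory conductance from interneuron j
  std::vector<std::vector<double>> sp_E(n_pyr), sp_I(n_int);
  std::vector<int> spiked_I(n_int, 0);

  const int nrp = record_pyr.size(), nri = record_int.size();
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix vrec_E(n_rec, nrp), vrec_I(n_rec, nri);
  NumericVector t_rec(n_rec), theta_rec(n_rec), x_rec(n_rec);

  double t_reset = 0.0;
  bool did_reset = false;
  const bool has_pert = (pert_off > pert_on);
  const double lat2 = lateral * lateral;
  int irec = 0;

  for (int s = 0; s <= n_steps; ++s) {
    const double t = s * dt;
    const double x = x0 + v * t;
    const double theta = om_theta * (t - t_reset);
    const bool in_pert = has_pert && t >= pert_on && t < pert_off;

    if (s % record_every == 0 && irec < n_rec) {
      t_rec[irec] = t;
      theta_rec[irec] = theta;
      x_rec[irec] = x;
      for (int k = 0; k < nrp; ++k) vrec_E(irec, k) = V_E[record_pyr[k]];
      for (int k = 0; k < nri; ++k) vrec_I(irec, k) = V_I[record_int[k]];
      ++irec;
    }
    if (s == n_steps) break;

    // interneuron update
    double I_drive_I = I0I - Itheta * std::cos(theta);
    if (in_pert) I_drive_I += pert_I_int;
    for (int j = 0; j < n_int; ++j) {
      double dV = (-(V_I[j] - E0_I) / tau_m_I
                   - gE[j] * (V_I[j] - E_rev_E) / Cm_I
                   + I_drive_I / Cm_I) * dt;
      if (noise_scale_I > 0.0) dV += noise_scale_I * norm_rand();
      V_I[j] += dV;
      if (V_I[j] >= Vth_I) {
        V_I[j] = Vr_I;
        sp_I[j].push_back(t + dt);
        spiked_I[j] = 1;
      } else {
        spiked_I[j] = 0;
      }
    }

    // pyramidal update (uses interneuron conductances from before this step's
    // decay; spikes increment conductances only after both populations update)
    bool any_pyr_spike = false;
    std::vector<int> pyr_spikes;
    for (int i = 0; i < n_pyr; ++i) {
      const double dx = x - xc[i];
      double I_drive_E = IE[i] * std::exp(-(dx * dx + lat2) /
                                          (2.0 * sigma_field * sigma_field));
      if (in_pert) I_drive_E += pert_I_pyr;
      double dV = (-(V_E[i] - E0_E) / tau_m_E
                   - gI[pyr2int[i]] * (V_E[i] - E_rev_I) / Cm_E
                   + I_drive_E / Cm_E) * dt;
      if (noise_scale_E > 0.0) dV += noise_scale_E * norm_rand();
      V_E[i] += dV;
      if (V_E[i] >= Vth_E) {
        V_E[i] = Vr_E;
        sp_E[i].push_back(t + dt);
        pyr_spikes.push_back(i);
        any_pyr_spike = true;
      }
    }

    // exact exponential conductance decay, then spike increments
    for (int j = 0; j < n_int; ++j) {
      gE[j] *= decE;
      gI[j] *= decI;
      if (spiked_I[j]) gI[j] += wI;
    }
    if (any_pyr_spike)
      for (int i : pyr_spikes) gE[pyr2int[i]] += wE;

    if (pert_reset && has_pert && !did_reset && (s + 1) * dt >= pert_on) {
      t_reset = pert_on;
      did_reset = true;
    }
  }

  List sp_E_out(n_pyr), sp_I_out(n_int);
  for (int i = 0; i < n_pyr; ++i) sp_E_out[i] = NumericVector(sp_E[i].begin(), sp_E[i].end());
  for (int j = 0; j < n_int; ++j) sp_I_out[j] = NumericVector(sp_I[j].begin(), sp_I[j].end());

  return List::create(_["spikes_pyr"] = sp_E_out, _["spikes_int"] = sp_I_out,
                      _["times"] = t_rec, _["v_pyr"] = vrec_E, _["v_int"] = vrec_I,
                      _["theta"] = theta_rec, _["x"] = x_rec,
                      _["reset_time"] = did_reset ? pert_on : NA_REAL);
}
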