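#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire membrane with an optional hyperpolarization-
// activated (sag) current and two spike-triggered after-currents.
//
// Subthreshold update is exponential-Euler at the sampling interval:
//   V_inf = E + rho * I_tot,  V <- V_inf + (V - V_inf) * exp(-dt/tau_m)
// with rho = R_leak / 1000 so that MOhm * pA gives mV.
// I_tot = injected + pacemaker + k_sag * s - a_f - a_s  (all pA).
// Sag activation s (mV) relaxes toward max(E - V, 0) with tau_sag.
// On threshold crossing a stereotyped spike waveform (`stamp`, mV
// relative to threshold) is written into the trace, the membrane is
// reset, and the after-current amplitudes are incremented.
//
// [[Rcpp::export]]
List lif_integrate(NumericVector i_inj, NumericVector noise, double dt_ms,
                   double e_rest, double tau_m, double rho,
                   double v_thr, double v_reset, double pacemaker,
                   double sag_k, double sag_tau,
                   double fahp_amp, double fahp_tau,
                   double sahp_amp, double sahp_tau, double sahp_tau_rise,
                   NumericVector stamp, int peak_offset, double v0) {
  const int n = i_inj.size();
  const int m = stamp.size();
  const bool has_noise = noise.size() == n;
  NumericVector out(n);
  std::vector<int> spike_peaks;   // 1-based indices of spike peaks
  std::vector<int> spike_onsets;  // 1-based indices of threshold crossings

  const double dm = std::exp(-dt_ms / tau_m);
  const double df = fahp_tau > 0 ? std::exp(-dt_ms / fahp_tau) : 0.0;
  const double ds = sahp_tau > 0 ? std::exp(-dt_ms / sahp_tau) : 0.0;
  const double dr = sahp_tau_rise > 0 ? std::exp(-dt_ms / sahp_tau_rise) : 0.0;
  // normalize the slow after-current (difference of exponentials) so
  // that each spike adds a peak of sahp_amp
  double s_gain = 1.0;
  if (sahp_amp > 0 && sahp_tau_rise > 0 && sahp_tau > sahp_tau_rise) {
    double tp = sahp_tau_rise * sahp_tau / (sahp_tau - sahp_tau_rise) *
                std::log(sahp_tau / sahp_tau_rise);
    s_gain = 1.0 / (std::exp(-tp / sahp_tau) - std::exp(-tp / sahp_tau_rise));
  }

  double v = v0, s = 0.0, af = 0.0, as_d = 0.0, as_r = 0.0;

  int i = 0;
  while (i < n) {
    double itot = i_inj[i] + pacemaker + sag_k * s - af - (as_d - as_r);
    double vinf = e_rest + rho * itot;
    v = vinf + (v - vinf) * dm;
    if (has_noise) v += noise[i];

    double drive = e_rest - v;
    if (drive < 0) drive = 0;
    if (sag_tau > 0) s += (dt_ms / sag_tau) * (drive - s);
    af *= df;
    as_d *= ds;
    as_r *= dr;

    if (v >= v_thr && m > 0) {
      spike_onsets.push_back(i + 1);
      int peak = i + peak_offset;
      if (peak >= n) peak = n - 1;
      spike_peaks.push_back(peak + 1);
      int j = 0;
      for (; j < m && i + j < n; ++j) {
        out[i + j] = v_thr + stamp[j];
        // after-currents keep decaying during the stamp
        af *= df;
        as_d *= ds;
        as_r *= dr;
      }
      i += j;
      v = v_reset;
      af += fahp_amp;
      as_d += sahp_amp * s_gain;
      as_r += sahp_amp * s_gain;
      s *= std::pow(1.0 - dt_ms / std::max(sag_tau, dt_ms), j); // deactivate during spike
      continue;
    }
    out[i] = v;
    ++i;
  }

  return List::create(_["v"] = out,
                      _["spike_peaks"] = wrap(spike_peaks),
                      _["spike_onsets"] = wrap(spike_onsets));
}
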