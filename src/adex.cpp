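#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the adaptive exponential integrate-and-fire
// model. Units: mV, ms, pA, pF, nS (g_L = 1000/R for R in MOhm). A spike is
// the sample where V first reaches v_peak; that sample is clipped to v_peak,
// the next starts from v_reset with w incremented by b.
//
// C dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T) - w + I(t)
// tau_w dw/dt = a (V - E_L) - w

// [[Rcpp::export(name = ".adex_integrate")]]
List adex_integrate(NumericVector i_cmd, double dt_ms,
                    double e_l, double r_mohm, double c_pf,
                    double v_t, double delta_t, double v_reset,
                    double v_peak, double tau_w, double a, double b,
                    double v0) {
  const int n = i_cmd.size();
  NumericVector v_out(n);
  IntegerVector spikes; // 1-based sample indices of spike peaks
  std::vector<int> spk;

  const double g_l = 1000.0 / r_mohm; // nS
  double v = v0;
  double w = a * (v0 - e_l);
  bool just_spiked = false;

  for (int k = 0; k < n; ++k) {
    if (just_spiked) {
      v = v_reset;
      w += b;
      just_spiked = false;
    }
    double arg = (v - v_t) / delta_t;
    if (arg > 30.0) arg = 30.0; // cap the exponential drive
    double i_ion = -g_l * (v - e_l) + g_l * delta_t * std::exp(arg) - w;
    double v_next = v + dt_ms / c_pf * (i_ion + i_cmd[k]);
    double w_next = w + dt_ms / tau_w * (a * (v - e_l) - w);
    if (v_next >= v_peak) {
      // the exponential blow-up past threshold is the spike; clip it
      v_next = v_peak;
      spk.push_back(k + 1);
      just_spiked = true;
    } else if (!std::isfinite(v_next) || std::fabs(v_next) > 1e4) {
      stop("simulation error: unstable integration (|V| > 1e4 mV)");
    }
    v_out[k] = v_next;
    v = v_next;
    w = w_next;
  }
  return List::create(_["v"] = v_out,
                      _["spike_idx"] = IntegerVector(spk.begin(), spk.end()));
}
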