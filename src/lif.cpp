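#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire integration by exponential Euler at the
// sampling step of the current trace. Voltage in mV, current in pA,
// r_in in MOhm (r_in * pA = microvolt * 1e3 -> divide by 1000 for mV).
// Threshold crossings are not interpolated (error <= dt).
// [[Rcpp::export(name = ".lif_integrate")]]
List lif_integrate(NumericVector current, double dt, double tau_m,
                   double r_in, double v_rest, double v_thresh,
                   double v_reset, double t_ref) {
  const int n = current.size();
  NumericVector v(n);
  std::vector<int> spikes;
  const double decay = std::exp(-dt / tau_m);
  const int ref_steps = (int)std::round(t_ref / dt);
  double vm = v_rest;
  int ref_left = 0;
  for (int i = 0; i < n; ++i) {
    if (ref_left > 0) {
      --ref_left;
      vm = v_reset;
    } else {
      const double vinf = v_rest + r_in * current[i] * 1e-3;
      vm = vinf + (vm - vinf) * decay;
      if (vm >= v_thresh) {
        spikes.push_back(i + 1); // 1-based sample index of the crossing
        vm = v_reset;
        ref_left = ref_steps;
      }
    }
    v[i] = vm;
  }
  return List::create(_["voltage"] = v, _["spike_idx"] = wrap(spikes));
}
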