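#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric slew filter for calcium activation kinetics: the output tracks
// the input instantaneously on the way down but rises as a first-order lag
// with rate k_act (1/s). Scaling the input scales the output (the switch
// condition is scale-invariant), which downstream code relies on to share
// one canonical curve across replicate spots.
// [[Rcpp::export]]
NumericVector slew_limit(NumericVector u, double k_act, double dt) {
  int n = u.size();
  NumericVector s(n);
  if (n == 0) return s;
  double a = 1.0 - std::exp(-k_act * dt);
  s[0] = a * u[0];
  for (int i = 1; i < n; ++i) {
    double prev = s[i - 1];
    if (u[i] > prev)
      s[i] = prev + a * (u[i] - prev);
    else
      s[i] = u[i];
  }
  return s;
}

// Asymmetric first-order tracking filter: relaxes toward the input with
// rate k_rise when below it and k_fall when above it. Calcium release is
// much faster than clearance, so rise and fall need independent rates.
// Also scale-invariant in the input.
// [[Rcpp::export]]
NumericVector asym_filter(NumericVector u, double k_rise, double k_fall,
                          double dt) {
  int n = u.size();
  NumericVector s(n);
  if (n == 0) return s;
  double ar = 1.0 - std::exp(-k_rise * dt);
  double af = 1.0 - std::exp(-k_fall * dt);
  double prev = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = (u[i] > prev) ? ar : af;
    prev = prev + a * (u[i] - prev);
    s[i] = prev;
  }
  return s;
}
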