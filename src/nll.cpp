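#include <Rcpp.h>
using namespace Rcpp;

// Sequential replay of one subject's trials. Q values (2 actions x 4 cues)
// reset to zero at every session boundary; parameters are indexed per
// session. Missing responses (NA) contribute no likelihood and no update.
// [[Rcpp::export]]
double nll_replay_cpp(IntegerVector cue, NumericVector valence,
                      IntegerVector go, NumericVector r,
                      IntegerVector session,
                      NumericVector rho, NumericVector epsilon,
                      NumericVector b, NumericVector pi_bias) {
  const int n = cue.size();
  double nll = 0.0;
  int cur = -1;
  double qgo[4], qng[4];
  for (int t = 0; t < n; ++t) {
    const int s = session[t] - 1;
    if (s != cur) {
      for (int k = 0; k < 4; ++k) { qgo[k] = 0.0; qng[k] = 0.0; }
      cur = s;
    }
    if (go[t] == NA_INTEGER) continue;
    const int c = cue[t] - 1;
    const double wgo = qgo[c] + b[s] + valence[t] * pi_bias[s];
    const double wng = qng[c];
    const double m = wgo > wng ? wgo : wng;
    const double eg = std::exp(wgo - m), en = std::exp(wng - m);
    const double pgo = eg / (eg + en);
    double p = (go[t] == 1) ? pgo : 1.0 - pgo;
    if (p < 1e-300) p = 1e-300;
    nll -= std::log(p);
    if (!NumericVector::is_na(r[t])) {
      if (go[t] == 1)
        qgo[c] += epsilon[s] * (rho[s] * r[t] - qgo[c]);
      else
        qng[c] += epsilon[s] * (rho[s] * r[t] - qng[c]);
    }
  }
  return nll;
}
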