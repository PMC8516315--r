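#include <Rcpp.h>
using namespace Rcpp;

// Teacher-forced Bernoulli log-likelihood of the double-trace family
// (dt / fq / fq_wc via zero scalings) over stacked sessions.
//
// cmat, rmat: trials x sessions matrices of recorded choices (1 = right)
// and rewards, zero-padded past each session's length; lens gives the
// true lengths; score flags the trials contributing to the total (CV
// masking). Probabilities are clamped to [1e-12, 1 - 1e-12] before the log.
// Returns c(total_log_lik, n_scored).

// [[Rcpp::export]]
NumericVector dt_family_ll_cpp(NumericMatrix cmat, NumericMatrix rmat,
                               IntegerVector lens, LogicalMatrix score,
                               double alpha, double beta, double tau_f,
                               double tau_s, double phi, double vth) {
  const int ns = cmat.ncol();
  double total = 0.0, cnt = 0.0;
  for (int j = 0; j < ns; ++j) {
    double ql = 0.0, qr = 0.0, fl = 0.5, fr = 0.5, sl = 0.5, sr = 0.5;
    const int T = lens[j];
    for (int t = 0; t < T; ++t) {
      const double h = (qr - ql) + phi * (fr - fl) + vth * (sr - sl);
      const double pr = 1.0 / (1.0 + std::exp(-beta * h));
      const double c = cmat(t, j);
      const double r = rmat(t, j);
      if (score(t, j)) {
        double pc = (c == 1.0) ? pr : 1.0 - pr;
        if (pc < 1e-12) pc = 1e-12;
        if (pc > 1.0 - 1e-12) pc = 1.0 - 1e-12;
        total += std::log(pc);
        cnt += 1.0;
      }
      const double dl = 1.0 - c, dr = c;
      ql += alpha * (dl * r - ql);
      qr += alpha * (dr * r - qr);
      fl += tau_f * (dl - fl);
      fr += tau_f * (dr - fr);
      sl += tau_s * (dl - sl);
      sr += tau_s * (dr - sr);
    }
  }
  return NumericVector::create(total, cnt);
}
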