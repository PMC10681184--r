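#include <Rcpp.h>
using namespace Rcpp;

// Three-level binary Hierarchical Gaussian Filter, run over a whole binary
// sequence.  Returns the one-step-ahead prediction (logit and probability
// scale) for every trial plus the posterior state trajectories.
//
// Level 2 is the logit-scale tendency of the tracked event; level 3 is its
// log-volatility.  The update is the usual variational mean-field scheme:
// precision-weighted prediction errors with a volatility-dependent learning
// rate.  pi3 must stay positive; a non-positive value signals an unusable
// (kappa, omega, theta) configuration and aborts.
// [[Rcpp::export]]
List hgf_filter_cpp(IntegerVector u,
                    double kappa, double omega, double theta,
                    double mu2_0, double sigma2_0,
                    double mu3_0, double sigma3_0) {
  const int n = u.size();
  NumericVector pred_logit(n), pred_prob(n);
  NumericVector mu2v(n), sigma2v(n), mu3v(n), sigma3v(n);

  double mu2 = mu2_0, sigma2 = sigma2_0, mu3 = mu3_0, sigma3 = sigma3_0;

  for (int k = 0; k < n; ++k) {
    pred_logit[k] = mu2;
    double p = 1.0 / (1.0 + std::exp(-mu2));
    pred_prob[k] = p;

    double d1 = (double)u[k] - p;          // level-1 prediction error
    double e  = std::exp(kappa * mu3 + omega);
    double v  = sigma2 + e;                // predicted level-2 variance
    double pi2 = 1.0 / v + p * (1.0 - p);  // posterior level-2 precision
    double sigma2_new = 1.0 / pi2;
    double mu2_new = mu2 + sigma2_new * d1;

    // volatility prediction error
    double dmu2 = mu2_new - mu2;
    double d2 = (sigma2_new + dmu2 * dmu2) / v - 1.0;

    double pihat3 = 1.0 / (sigma3 + theta);
    double w2 = e / v;
    double r2 = (e - sigma2) / v;
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + r2 * d2);
    if (pi3 <= 0.0)
      stop("level-3 precision became non-positive at trial %d; "
           "check kappa/omega/theta", k + 1);
    double sigma3_new = 1.0 / pi3;
    double mu3_new = mu3 + 0.5 * kappa * sigma3_new * w2 * d2;

    mu2 = mu2_new; sigma2 = sigma2_new;
    mu3 = mu3_new; sigma3 = sigma3_new;
    mu2v[k] = mu2; sigma2v[k] = sigma2;
    mu3v[k] = mu3; sigma3v[k] = sigma3;
  }

  return List::create(_["pred_logit"] = pred_logit,
                      _["pred_prob"]  = pred_prob,
                      _["mu2"] = mu2v, _["sigma2"] = sigma2v,
                      _["mu3"] = mu3v, _["sigma3"] = sigma3v);
}
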