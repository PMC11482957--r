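#include <Rcpp.h>
using namespace Rcpp;

// Residual sum of squares of the power/logistic cue-value weighting model,
// evaluated over all trials of one participant x modality. Hot path of the
// bounded least-squares fit; the R implementation in expectation.R is the
// reference for predictions.
//
// x:  n x 10 rescaled, demeaned cue deviations
// la: log(pmax(|x|, eps)), precomputed once per fit
// v:  n x 10 cue values on the 0-100 scale
// y:  observed expectation ratings
// [[Rcpp::export(name = ".expectation_rss_cpp")]]
double expectation_rss_cpp(double k, double b, NumericMatrix x,
                           NumericMatrix la, NumericMatrix v,
                           NumericVector y) {
  const int n = x.nrow(), p = x.ncol();
  if (p > 32) stop("at most 32 cue values per trial are supported");
  double rss = 0.0;
  double u[32], s[32];
  for (int i = 0; i < n; ++i) {
    // power weights via a log-space softmax so extreme k cannot overflow
    double mx = R_NegInf;
    for (int j = 0; j < p; ++j) {
      const double e = (k - 1.0) * la(i, j);
      if (e > mx) mx = e;
    }
    double su = 0.0;
    for (int j = 0; j < p; ++j) {
      u[j] = std::exp((k - 1.0) * la(i, j) - mx);
      su += u[j];
    }
    double tot = 0.0, num = 0.0;
    for (int j = 0; j < p; ++j) {
      const double c = 1.0 / (1.0 + std::exp(-b * x(i, j)));
      s[j] = u[j] / su + c;
      tot += s[j];
      num += v(i, j) * s[j];
    }
    const double r = num / tot - y[i];
    rss += r * r;
  }
  return rss;
}
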