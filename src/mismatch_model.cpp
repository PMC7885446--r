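// Sudden-expansion mismatch model: equilibrium and transient distributions
// and the SSD objective used by the least-squares fitter. The objective is
// evaluated hundreds of times per fit and tens of thousands of times per
// parametric bootstrap, hence the compiled kernel.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Equilibrium mismatch distribution F_d(theta) = theta^d / (theta+1)^(d+1).
static void equilibrium(double theta, int dmax, std::vector<double> &out) {
  out.assign(dmax + 1, 0.0);
  if (theta <= 0.0) {
    out[0] = 1.0;
    return;
  }
  double ratio = theta / (theta + 1.0);
  double cur = 1.0 / (theta + 1.0);
  for (int d = 0; d <= dmax; ++d) {
    out[d] = cur;
    cur *= ratio;
  }
}

static void transient(double tau, double theta0, double theta1, int dmax,
                      std::vector<double> &out) {
  std::vector<double> f0, f1;
  if (theta1 < 1e-12) theta1 = 1e-12;
  equilibrium(theta0, dmax, f0);
  equilibrium(theta1, dmax, f1);
  out.assign(dmax + 1, 0.0);
  if (tau <= 0.0) {
    for (int d = 0; d <= dmax; ++d) out[d] = f0[d];
    return;
  }
  // w_i = exp(-tau (theta1+1)/theta1) tau^i / i!, computed in log space so
  // large tau never overflows.
  double lt = std::log(tau);
  double c = -tau * (theta1 + 1.0) / theta1;
  std::vector<double> w(dmax + 1);
  for (int i = 0; i <= dmax; ++i)
    w[i] = std::exp(c + i * lt - std::lgamma(i + 1.0));
  for (int d = 0; d <= dmax; ++d) {
    double s = 0.0;
    for (int i = 0; i <= d; ++i) s += w[i] * (f0[d - i] - f1[d - i]);
    out[d] = f1[d] + s;
    // the algebra is non-negative; far tails can round to ~ -1e-20
    if (out[d] < 0.0) out[d] = 0.0;
  }
}

// [[Rcpp::export(name = ".expected_mismatch_cpp")]]
NumericVector expected_mismatch_cpp(double tau, double theta0, double theta1,
                                    int dmax) {
  std::vector<double> f;
  transient(tau, theta0, theta1, dmax, f);
  NumericVector out(dmax + 1);
  for (int d = 0; d <= dmax; ++d) out[d] = f[d];
  return out;
}

// SSD between an observed frequency vector on 0..dmax and the model
// expectation, with the model's residual mass beyond dmax compared against
// an empty observed tail bin.
// [[Rcpp::export(name = ".ssd_sudden_cpp")]]
double ssd_sudden_cpp(double tau, double theta0, double theta1,
                      NumericVector obs_freq) {
  int dmax = obs_freq.size() - 1;
  std::vector<double> f;
  transient(tau, theta0, theta1, dmax, f);
  double ssd = 0.0, total = 0.0;
  for (int d = 0; d <= dmax; ++d) {
    double e = f[d] - obs_freq[d];
    ssd += e * e;
    total += f[d];
  }
  double tail = 1.0 - total;
  if (tail < 0.0) tail = 0.0;
  ssd += tail * tail;
  return ssd;
}
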