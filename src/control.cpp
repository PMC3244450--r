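#include <Rcpp.h>
using namespace Rcpp;

// Conflict-monitoring recursion. C[0] = c0 and, for t >= 1,
//   C[t] = (1 - lambda) * C[t-1] + lambda * (alpha * E[t-1] + beta)
// so control on a trial is driven by the conflict registered on the
// previous trial. Kept in one place so the trajectory and the
// summary-statistic paths apply floating-point operations in the same
// order.

// [[Rcpp::export]]
NumericVector cpp_control_trajectory(IntegerVector conflict, double lambda,
                                     double beta, double alpha, double c0) {
  int n = conflict.size();
  NumericVector C(n);
  if (n == 0) return C;
  C[0] = c0;
  for (int t = 1; t < n; ++t) {
    C[t] = (1.0 - lambda) * C[t - 1] +
           lambda * (alpha * conflict[t - 1] + beta);
  }
  return C;
}

// Mean control over all trials plus mean adaptation (mean control on
// trials whose previous trial carried conflict minus trials whose
// previous trial did not). Returns c(mean_control, mean_adaptation,
// n_post_conflict, n_post_no_conflict); adaptation is NA when one
// previous-trial class is empty.

// [[Rcpp::export]]
NumericVector cpp_control_stats(IntegerVector conflict, double lambda,
                                double beta, double alpha, double c0) {
  int n = conflict.size();
  double c = c0, total = c0, s1 = 0.0, s0 = 0.0;
  int n1 = 0, n0 = 0;
  for (int t = 1; t < n; ++t) {
    int e = conflict[t - 1];
    c = (1.0 - lambda) * c + lambda * (alpha * e + beta);
    total += c;
    if (e == 1) {
      s1 += c;
      ++n1;
    } else {
      s0 += c;
      ++n0;
    }
  }
  double adapt = (n1 > 0 && n0 > 0) ? (s1 / n1 - s0 / n0) : NA_REAL;
  double mc = (n > 0) ? total / n : NA_REAL;
  return NumericVector::create(mc, adapt, (double)n1, (double)n0);
}
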