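#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-matching kernels for the embedding entropies. Both kernels use
// N - m templates so that every length-m template has a length-(m + 1)
// extension, the Richman-Moorman convention. Self-matches are excluded and
// r is an absolute tolerance (callers rescale by the series SD).

// Counts B (length-m template pairs within Chebyshev tolerance r) and A
// (length-(m+1) pairs). Returned as doubles: pair counts can exceed
// .Machine$integer.max for long records.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::abs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        B += 1.0;
        double a = std::abs(x[i + m] - x[j + m]);
        if (a > d) d = a;
        if (d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// d^nexp with fast paths for the integer exponents of the study grid; a
// similarity below exp(-46) (~1e-20) contributes nothing at double
// precision, so such pairs short-circuit to 0.
static inline double powint(double d, double nexp) {
  if (nexp == 1.0) return d;
  if (nexp == 2.0) return d * d;
  if (nexp == 3.0) return d * d * d;
  return std::pow(d, nexp);
}

static inline double similarity(double d, double nexp, double r) {
  const double t = powint(d, nexp) / r;
  return t > 46.0 ? 0.0 : std::exp(-t);
}

// Average fuzzy similarity phi_m and phi_{m+1}: similarity is
// exp(-d^nexp / r) with d the Chebyshev distance between templates.
// When baseline is true each template has its own mean subtracted first.
// [[Rcpp::export]]
NumericVector fuzzy_phis(NumericVector x, int m, double r, double nexp,
                         bool baseline) {
  const int N = x.size();
  const int nt = N - m;
  std::vector<double> mu_m(nt), mu_m1(nt);
  if (baseline) {
    for (int i = 0; i < nt; ++i) {
      double s = 0.0;
      for (int k = 0; k < m; ++k) s += x[i + k];
      mu_m[i] = s / m;
      mu_m1[i] = (s + x[i + m]) / (m + 1);
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0, d1 = 0.0;
      const double bi = baseline ? mu_m[i] : 0.0;
      const double bj = baseline ? mu_m[j] : 0.0;
      const double ci = baseline ? mu_m1[i] : 0.0;
      const double cj = baseline ? mu_m1[j] : 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::abs((x[i + k] - bi) - (x[j + k] - bj));
        if (a > d) d = a;
        double b = std::abs((x[i + k] - ci) - (x[j + k] - cj));
        if (b > d1) d1 = b;
      }
      {
        double b = std::abs((x[i + m] - ci) - (x[j + m] - cj));
        if (b > d1) d1 = b;
      }
      phi_m += similarity(d, nexp, r);
      phi_m1 += similarity(d1, nexp, r);
    }
  }
  const double npairs = 0.5 * nt * (nt - 1.0);
  return NumericVector::create(_["phi_m"] = phi_m / npairs,
                               _["phi_m1"] = phi_m1 / npairs);
}
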