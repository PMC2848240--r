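#include <Rcpp.h>
using namespace Rcpp;

// Two-state HBD hidden Markov chain along the genetic map.
// State 1 = HBD, state 0 = non-HBD. With r = exp(-a * d):
//   P(HBD->HBD)   = r + f(1-r)     P(HBD->non)   = (1-f)(1-r)
//   P(non->HBD)   = f(1-r)         P(non->non)   = r + (1-f)(1-r)
// Stationary distribution (f, 1-f); chromosomes start at stationarity and
// contribute independent log-likelihood terms. Scaled forward recursion:
// alpha is renormalised at every marker, the log of the normaliser
// accumulates into the log-likelihood (plain forward underflows on long
// chromosomes).

// [[Rcpp::export]]
double hmm_forward_loglik_cpp(NumericVector ehbd, NumericVector enon,
                              NumericVector dist, LogicalVector newchrom,
                              double f, double a) {
  const int L = ehbd.size();
  double ll = 0.0, a1 = 0.0, a0 = 0.0;
  double last_d = -1.0, r = 0.0;
  for (int i = 0; i < L; ++i) {
    double n1, n0;
    if (newchrom[i]) {
      n1 = f * ehbd[i];
      n0 = (1.0 - f) * enon[i];
    } else {
      double d = dist[i];
      if (d != last_d) { r = std::exp(-a * d); last_d = d; }
      double p11 = r + f * (1.0 - r), p10 = (1.0 - f) * (1.0 - r);
      double p01 = f * (1.0 - r),     p00 = r + (1.0 - f) * (1.0 - r);
      n1 = (a1 * p11 + a0 * p01) * ehbd[i];
      n0 = (a1 * p10 + a0 * p00) * enon[i];
    }
    double s = n1 + n0;
    if (!(s > 0.0)) return R_NegInf;
    ll += std::log(s);
    a1 = n1 / s;
    a0 = n0 / s;
  }
  return ll;
}

// Forward-backward smoothing: P(state = HBD at marker i | all genotypes on
// the chromosome). Beta is scaled by the same per-marker normalisers as
// alpha and resets to 1 at chromosome ends.

// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericVector ehbd, NumericVector enon,
                              NumericVector dist, LogicalVector newchrom,
                              double f, double a) {
  const int L = ehbd.size();
  NumericVector al1(L), al0(L), cs(L), post(L);
  double ll = 0.0, last_d = -1.0, r = 0.0;
  for (int i = 0; i < L; ++i) {
    double n1, n0;
    if (newchrom[i]) {
      n1 = f * ehbd[i];
      n0 = (1.0 - f) * enon[i];
    } else {
      double d = dist[i];
      if (d != last_d) { r = std::exp(-a * d); last_d = d; }
      double p11 = r + f * (1.0 - r), p10 = (1.0 - f) * (1.0 - r);
      double p01 = f * (1.0 - r),     p00 = r + (1.0 - f) * (1.0 - r);
      n1 = (al1[i - 1] * p11 + al0[i - 1] * p01) * ehbd[i];
      n0 = (al1[i - 1] * p10 + al0[i - 1] * p00) * enon[i];
    }
    double s = n1 + n0;
    if (!(s > 0.0)) return List::create(_["loglik"] = R_NegInf,
                                        _["posterior"] = post,
                                        _["bad_marker"] = i + 1);
    ll += std::log(s);
    cs[i] = s;
    al1[i] = n1 / s;
    al0[i] = n0 / s;
  }
  double b1 = 1.0, b0 = 1.0;
  last_d = -1.0;
  for (int i = L - 1; i >= 0; --i) {
    bool chrom_end = (i == L - 1) || newchrom[i + 1];
    if (chrom_end) {
      b1 = 1.0; b0 = 1.0;
    } else {
      double d = dist[i + 1];
      if (d != last_d) { r = std::exp(-a * d); last_d = d; }
      double p11 = r + f * (1.0 - r), p10 = (1.0 - f) * (1.0 - r);
      double p01 = f * (1.0 - r),     p00 = r + (1.0 - f) * (1.0 - r);
      double nb1 = (p11 * ehbd[i + 1] * b1 + p10 * enon[i + 1] * b0) / cs[i + 1];
      double nb0 = (p01 * ehbd[i + 1] * b1 + p00 * enon[i + 1] * b0) / cs[i + 1];
      b1 = nb1; b0 = nb0;
    }
    double u1 = al1[i] * b1, u0 = al0[i] * b0;
    post[i] = u1 / (u1 + u0);
  }
  return List::create(_["loglik"] = ll, _["posterior"] = post,
                      _["bad_marker"] = -1);
}
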