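#include <Rcpp.h>
#include "kimura.h"
#include "lineage.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".kimura_density_cpp")]]
NumericVector kimura_density_cpp(double p, double tau, NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = esr::kim_density(p, tau, x[i]);
  return out;
}

// [[Rcpp::export(name = ".kimura_boundary_cpp")]]
NumericVector kimura_boundary_cpp(double p, double tau) {
  double lost, fixed;
  esr::kim_boundary(p, tau, lost, fixed);
  return NumericVector::create(_["lost"] = lost, _["fixed"] = fixed);
}

// [[Rcpp::export(name = ".kimura_log_kernel_cpp")]]
NumericVector kimura_log_kernel_cpp(double p, double tau, NumericVector x,
                                    double atom_width) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = esr::kim_log_kernel(p, tau, x[i], atom_width);
  return out;
}

// [[Rcpp::export(name = ".lineage_thin_cpp")]]
List lineage_thin_cpp(int i, double tau) {
  esr::LinDist d = esr::lineage_thin(i, tau);
  return List::create(_["kmin"] = d.kmin, _["probs"] = NumericVector(d.p.begin(), d.p.end()));
}

// [[Rcpp::export(name = ".lineage_moments_cpp")]]
NumericVector lineage_moments_cpp(int i, double tau) {
  double m, v;
  esr::lineage_moments(i, tau, m, v);
  return NumericVector::create(_["mean"] = m, _["var"] = v);
}

// [[Rcpp::export(name = ".lineage_convolve_cpp")]]
List lineage_convolve_cpp(int kmin1, NumericVector p1, int kmin2, NumericVector p2) {
  esr::LinDist a, b;
  a.kmin = kmin1; a.p.assign(p1.begin(), p1.end());
  b.kmin = kmin2; b.p.assign(p2.begin(), p2.end());
  esr::LinDist c = esr::lineage_convolve(a, b);
  return List::create(_["kmin"] = c.kmin, _["probs"] = NumericVector(c.p.begin(), c.p.end()));
}

// [[Rcpp::export(name = ".lineage_root_cpp")]]
List lineage_root_cpp(IntegerVector parent0, int nleaf, NumericVector tau,
                      IntegerVector nsam) {
  std::vector<int> par(parent0.begin(), parent0.end());
  std::vector<double> tv(tau.begin(), tau.end());
  std::vector<int> ns(nsam.begin(), nsam.end());
  esr::LinDist d = esr::lineage_root_distribution(par, nleaf, tv, ns);
  return List::create(_["kmin"] = d.kmin, _["probs"] = NumericVector(d.p.begin(), d.p.end()));
}

// [[Rcpp::export(name = ".prob_poly_cpp")]]
NumericVector prob_poly_cpp(int kmin, NumericVector probs, NumericVector x) {
  esr::LinDist d;
  d.kmin = kmin; d.p.assign(probs.begin(), probs.end());
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] <= 0.0 || x[i] >= 1.0) { out[i] = 0.0; continue; }
    out[i] = std::exp(esr::log_prob_poly(d, x[i]));
  }
  return out;
}
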