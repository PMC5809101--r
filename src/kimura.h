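#ifndef ESRTREE_KIMURA_H
#define ESRTREE_KIMURA_H

#include <vector>
#include <cmath>
#include <limits>

// Kimura's time-dependent pure-drift diffusion on [0,1], written in terms of
// Gegenbauer polynomials C^{3/2}_{i-1}(z), z = 1 - 2p.  Time is tau = t/(2Ne).
// Below KIM_TAU_GAUSS the eigen-series needs hundreds of terms and loses
// accuracy, so a censored-Gaussian surrogate with the exact drift mean (p) and
// variance p(1-p)(1-exp(-tau)) is used instead.

namespace esr {

constexpr double KIM_TAU_GAUSS = 0.005;

// number of series terms needed so that exp(-i(i+1)tau/2) < exp(-21)
inline int kim_nterms(double tau) {
  double i = (-1.0 + std::sqrt(1.0 + 168.0 / tau)) / 2.0;
  int n = (int)std::ceil(i);
  if (n < 5) n = 5;
  if (n > 500) n = 500;
  return n;
}

// cached eigenvalue factors exp(-i(i+1)tau/2), i = 1..nt; the sampler cycles
// through a handful of tau values between branch updates, so a small
// exact-match cache removes nearly all exp() calls from the hot path
inline const std::vector<double> &kim_exp_table(double tau, int nt) {
  static thread_local std::vector<std::pair<double, std::vector<double>>> cache;
  for (auto &e : cache)
    if (e.first == tau && (int)e.second.size() > nt) return e.second;
  std::vector<double> v(nt + 1);
  v[0] = 1.0;
  for (int i = 1; i <= nt; ++i) v[i] = std::exp(-0.5 * i * (i + 1) * tau);
  if (cache.size() >= 24) cache.erase(cache.begin());
  cache.emplace_back(tau, std::move(v));
  return cache.back().second;
}

// fill C[m] = C^{3/2}_m(z) for m = 0..nmax
inline void kim_geg(double z, int nmax, std::vector<double> &C) {
  C.resize(nmax + 1);
  C[0] = 1.0;
  if (nmax >= 1) C[1] = 3.0 * z;
  for (int m = 2; m <= nmax; ++m)
    C[m] = ((2.0 * m + 1.0) * z * C[m - 1] - (m + 1.0) * C[m - 2]) / m;
}

inline double norm_cdf(double x) { return 0.5 * std::erfc(-x / std::sqrt(2.0)); }

// continuous density on (0,1); exact 0 when p is 0 or 1
inline double kim_density(double p, double tau, double x) {
  if (p <= 0.0 || p >= 1.0) return 0.0;
  double q = 1.0 - p;
  if (tau < KIM_TAU_GAUSS) {
    double s2 = p * q * (-std::expm1(-tau));
    double s = std::sqrt(s2);
    double d = (x - p) / s;
    return std::exp(-0.5 * d * d) / (s * std::sqrt(2.0 * M_PI));
  }
  int nt = kim_nterms(tau);
  const std::vector<double> &E = kim_exp_table(tau, nt);
  // fused three-term recurrences for C^{3/2}_{i-1}(1-2p) and (1-2x)
  double zp = 1.0 - 2.0 * p, zx = 1.0 - 2.0 * x;
  double cp0 = 1.0, cp1 = 3.0 * zp, cx0 = 1.0, cx1 = 3.0 * zx;
  double s = 4.0 * p * q * (3.0 / 2.0) * E[1];  // i = 1 term (C_0 = 1)
  double cp = cp1, cx = cx1;
  for (int i = 2; i <= nt; ++i) {
    s += 4.0 * p * q * (2.0 * i + 1.0) / (double)(i * (i + 1)) * cp * cx * E[i];
    double m = (double)i;  // next degree
    double cp2 = ((2.0 * m + 1.0) * zp * cp1 - (m + 1.0) * cp0) / m;
    double cx2 = ((2.0 * m + 1.0) * zx * cx1 - (m + 1.0) * cx0) / m;
    cp0 = cp1; cp1 = cp2; cx0 = cx1; cx1 = cx2;
    cp = cp1; cx = cx1;
  }
  return s > 0.0 ? s : 0.0;
}

// absorption masses at 0 (lost) and 1 (fixed) by time tau
inline void kim_boundary(double p, double tau, double &lost, double &fixed) {
  if (p <= 0.0) { lost = 1.0; fixed = 0.0; return; }
  if (p >= 1.0) { lost = 0.0; fixed = 1.0; return; }
  double q = 1.0 - p;
  if (tau <= 0.0) { lost = 0.0; fixed = 0.0; return; }
  if (tau < KIM_TAU_GAUSS) {
    double s = std::sqrt(p * q * (-std::expm1(-tau)));
    lost = norm_cdf((0.0 - p) / s);
    fixed = 1.0 - norm_cdf((1.0 - p) / s);
    return;
  }
  int nt = kim_nterms(tau);
  const std::vector<double> &E = kim_exp_table(tau, nt);
  double zp = 1.0 - 2.0 * p, zq = -zp;
  double cp0 = 1.0, cp1 = 3.0 * zp, cq0 = 1.0, cq1 = 3.0 * zq;
  double fx = p, ls = q, sgn = -1.0;
  double cp = 1.0, cq = 1.0;  // C_0 for the i = 1 term
  for (int i = 1; i <= nt; ++i) {
    double w = (2.0 * i + 1.0) * p * q * 2.0 / (double)(i * (i + 1)) * E[i];
    fx += sgn * w * cp;   // fixation uses F(1-i,i+2,2,p)
    ls += sgn * w * cq;   // loss is fixation of the complement allele
    sgn = -sgn;
    if (i == 1) { cp = cp1; cq = cq1; continue; }
    double m = (double)i;
    double cp2 = ((2.0 * m + 1.0) * zp * cp1 - (m + 1.0) * cp0) / m;
    double cq2 = ((2.0 * m + 1.0) * zq * cq1 - (m + 1.0) * cq0) / m;
    cp0 = cp1; cp1 = cp2; cq0 = cq1; cq1 = cq2;
    cp = cp1; cq = cq1;
  }
  lost = ls < 0.0 ? 0.0 : (ls > 1.0 ? 1.0 : ls);
  fixed = fx < 0.0 ? 0.0 : (fx > 1.0 ? 1.0 : fx);
}

// log of the mixed kernel evaluated as a bona fide density on [0,1]: the
// absorption atoms are smeared uniformly over boundary strips of width atom_w
// and added on top of the continuous part, so the result integrates to one for
// every (p, tau) and Metropolis ratios across the mixed space are well defined.
// A parent inside a strip counts as absorbed and can only transition to the
// same strip: without this rule, "lost" alleles could re-emerge at O(1)
// probability, which makes the polymorphism-conditioned posterior improper
// (the 1/P(lambda=1|x_r) reward for driving x_r to 0 would be unbounded).
inline double kim_log_kernel(double p, double tau, double x, double atom_w) {
  if (p < atom_w)
    return x < atom_w ? -std::log(atom_w)
                      : -std::numeric_limits<double>::infinity();
  if (p > 1.0 - atom_w)
    return x > 1.0 - atom_w ? -std::log(atom_w)
                            : -std::numeric_limits<double>::infinity();
  double d = kim_density(p, tau, x);
  if (x < atom_w || x > 1.0 - atom_w) {
    double lost, fixed;
    kim_boundary(p, tau, lost, fixed);
    if (x < atom_w) d += lost / atom_w;
    if (x > 1.0 - atom_w) d += fixed / atom_w;
  }
  return d > 0.0 ? std::log(d) : -std::numeric_limits<double>::infinity();
}

} // namespace esr

#endif
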