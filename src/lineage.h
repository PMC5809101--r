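#ifndef ESRTREE_LINEAGE_H
#define ESRTREE_LINEAGE_H

#include <vector>
#include <cmath>
#include "kimura.h"

// Distribution of the number of ancestral lineages of a sample, used to
// compute the probability that a site is polymorphic in the pooled sample.
// The pure-death coalescent chain (k -> k-1 at rate k(k-1)/2 on the diffusion
// time scale) is approximated by a normal distribution discretised on
// half-integer boundaries and clamped to [1, i]; its mean and variance are the
// exact moments of the chain, computed from the stable positive-term sums
//   E[A]   = sum_i c_i,           c_i = exp(-i(i-1)tau/2) (2i-1) n_(i)/n^(i)
//   E[A^2] = sum_i c_i (i^2-i+1)
// with n_(i)/n^(i) the falling/rising factorial ratio.

namespace esr {

struct LinDist {
  int kmin = 1;
  std::vector<double> p;  // probs for k = kmin, kmin+1, ...
};

inline void lineage_moments(int n, double tau, double &mean, double &var) {
  double m1 = 0.0, m2 = 0.0, r = 1.0;  // r = n_(i)/n^(i), starts at i=1
  for (int i = 1; i <= n; ++i) {
    if (i > 1) r *= (double)(n - i + 1) / (double)(n + i - 1);
    double c = std::exp(-0.5 * i * (i - 1) * tau) * (2.0 * i - 1.0) * r;
    m1 += c;
    m2 += c * (double)(i * (i - 1) + 1);
    if (c < 1e-14 * (m1 > 1.0 ? m1 : 1.0) && i > 2) break;
  }
  mean = m1;
  var = m2 - m1 * m1;
  if (var < 0.0) var = 0.0;
}

// log n! for integer arguments (memoised); the exact thinning below only
// ever needs factorials of small integers
inline double lfact(int n) {
  static thread_local std::vector<double> lf{0.0, 0.0};
  while ((int)lf.size() <= n) lf.push_back(lf.back() + std::log((double)lf.size()));
  return lf[n];
}

// exact Tavare distribution (alternating series; stable for small i)
inline LinDist lineage_thin_exact(int i, double tau) {
  LinDist d;
  d.kmin = 1;
  d.p.assign(i, 0.0);
  double tot = 0.0;
  for (int k = 1; k <= i; ++k) {
    double s = 0.0;
    for (int m = k; m <= i; ++m) {
      double lt = -0.5 * m * (m - 1) * tau + std::log(2.0 * m - 1.0) +
                  lfact(k + m - 2) - lfact(k - 1) - lfact(k) - lfact(m - k) +
                  lfact(i) - lfact(i - m) - (lfact(i + m - 1) - lfact(i - 1));
      s += (((m - k) % 2) ? -1.0 : 1.0) * std::exp(lt);
    }
    if (s < 0.0) s = 0.0;
    d.p[k - 1] = s;
    tot += s;
  }
  if (tot > 0.0) for (auto &x : d.p) x /= tot;
  return d;
}

constexpr int LIN_EXACT_MAX = 20;

// distribution of the number of ancestral lineages of i lineages after tau:
// exact for small i, moment-matched normal approximation otherwise
inline LinDist lineage_thin(int i, double tau) {
  LinDist d;
  if (i <= 1 || tau <= 0.0) {
    d.kmin = i < 1 ? 1 : i;
    d.p.assign(1, 1.0);
    return d;
  }
  if (i <= LIN_EXACT_MAX) return lineage_thin_exact(i, tau);
  double m, v;
  lineage_moments(i, tau, m, v);
  double s = std::sqrt(v);
  d.kmin = 1;
  d.p.assign(i, 0.0);
  if (s < 1e-8) {
    int k = (int)std::lround(m);
    if (k < 1) k = 1;
    if (k > i) k = i;
    d.p[k - 1] = 1.0;
    return d;
  }
  double tot = 0.0;
  for (int k = 1; k <= i; ++k) {
    double hi = (k == i) ? 1.0 : norm_cdf((k + 0.5 - m) / s);
    double lo = (k == 1) ? 0.0 : norm_cdf((k - 0.5 - m) / s);
    double pk = hi - lo;  // tails are clamped into k=1 and k=i
    if (pk < 0.0) pk = 0.0;
    d.p[k - 1] = pk;
    tot += pk;
  }
  if (tot > 0.0) for (auto &x : d.p) x /= tot;
  return d;
}

// drop negligible tails (keeps >= 1 - 2e-12 of the mass), renormalise
inline void lineage_trim(LinDist &d) {
  size_t a = 0, b = d.p.size();
  double tail = 0.0;
  while (b > a + 1 && tail + d.p[b - 1] < 1e-12) { tail += d.p[b - 1]; --b; }
  tail = 0.0;
  while (a + 1 < b && tail + d.p[a] < 1e-12) { tail += d.p[a]; ++a; }
  if (a > 0 || b < d.p.size()) {
    std::vector<double> q(d.p.begin() + a, d.p.begin() + b);
    d.p.swap(q);
    d.kmin += (int)a;
  }
  double tot = 0.0;
  for (double x : d.p) tot += x;
  if (tot > 0.0) for (auto &x : d.p) x /= tot;
}

// convolution: number of lineages entering a node from independent daughters
inline LinDist lineage_convolve(const LinDist &a, const LinDist &b) {
  LinDist c;
  c.kmin = a.kmin + b.kmin;
  c.p.assign(a.p.size() + b.p.size() - 1, 0.0);
  for (size_t i = 0; i < a.p.size(); ++i) {
    if (a.p[i] == 0.0) continue;
    for (size_t j = 0; j < b.p.size(); ++j)
      c.p[i + j] += a.p[i] * b.p[j];
  }
  lineage_trim(c);
  return c;
}

// thinning applied to a distribution of lineage counts (mixture over k)
inline LinDist lineage_thin_dist(const LinDist &d, double tau) {
  if (tau <= 0.0) return d;
  int kmax = d.kmin + (int)d.p.size() - 1;
  LinDist out;
  out.kmin = 1;
  out.p.assign(kmax, 0.0);
  for (size_t j = 0; j < d.p.size(); ++j) {
    double w = d.p[j];
    if (w < 1e-14) continue;
    LinDist t = lineage_thin(d.kmin + (int)j, tau);
    for (size_t l = 0; l < t.p.size(); ++l)
      out.p[t.kmin + (int)l - 1] += w * t.p[l];
  }
  lineage_trim(out);
  return out;
}

// root-node lineage-count distribution for one genetic system.
// parent[i] (0-based, length nnode, parent[root] = -1); nodes must be ordered
// so every child index < its parent index (leaves 0..I-1, internals postorder).
// tau[i] is the branch length above node i; nsam[i] the leaf sample sizes.
inline LinDist lineage_root_distribution(const std::vector<int> &parent,
                                         int nleaf,
                                         const std::vector<double> &tau,
                                         const std::vector<int> &nsam) {
  int nnode = (int)parent.size();
  std::vector<LinDist> at(nnode);       // convolution of daughters at node i
  std::vector<bool> has(nnode, false);
  for (int i = 0; i < nnode; ++i) {
    LinDist cur;
    if (i < nleaf) cur = lineage_thin(nsam[i], tau[i]);
    else {
      cur = at[i];
      if (parent[i] >= 0) cur = lineage_thin_dist(cur, tau[i]);
    }
    if (parent[i] < 0) return cur;      // root: no thinning above the root
    int pa = parent[i];
    if (!has[pa]) { at[pa] = cur; has[pa] = true; }
    else at[pa] = lineage_convolve(at[pa], cur);
  }
  return at[nnode - 1];                 // not reached
}

// log P(site polymorphic | root frequency x, root lineage-count distribution)
inline double log_prob_poly(const LinDist &d, double x) {
  if (x <= 0.0 || x >= 1.0) return -std::numeric_limits<double>::infinity();
  // sum_k p_k z^k via Horner from the top of the support
  double gx = 0.0, gq = 0.0, q = 1.0 - x;
  for (size_t j = d.p.size(); j-- > 0;) {
    gx = gx * x + d.p[j];
    gq = gq * q + d.p[j];
  }
  if (d.kmin < 32) {  // kmin is the number of root daughters: always small
    for (int m = 0; m < d.kmin; ++m) { gx *= x; gq *= q; }
  } else {
    gx *= std::pow(x, (double)d.kmin);
    gq *= std::pow(q, (double)d.kmin);
  }
  double pp = 1.0 - gx - gq;
  if (pp < 1e-300) pp = 1e-300;
  return std::log(pp);
}

} // namespace esr

#endif
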