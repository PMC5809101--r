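#include <Rcpp.h>
#include <vector>
#include <string>
#include "kimura.h"
#include "lineage.h"

using namespace Rcpp;

// Component-wise Metropolis-within-Gibbs sampler for the joint posterior over
// both genetic systems (autosomal, X-linked): latent allele frequencies at
// every node x SNP, per-branch drift times (tau_A, tau_X) restricted to the
// wedge 9 tau_X / 16 < tau_A < 9 tau_X / 8, and root-beta hyper-parameters
// (mu, nu) per system.  The likelihood is optionally conditioned on SNP
// polymorphism through the root lineage-count distribution.

namespace {

struct Sys {
  int J = 0;
  std::vector<double> y, n;       // leaf counts, I x J (row-major node*J + j)
  std::vector<double> lchoose_sum; // per snp sum of log C(n,y) (deviance const)
  std::vector<int> nmaxleaf;      // per-leaf lineage counts (max sample size)
  double atom_w = 0.005;
  std::vector<double> x;          // nnode x J
  std::vector<double> tau;        // nnode (root entry unused)
  double mu = 0.5, nu = 2.0;
  std::vector<double> logK;       // nnode x J, branch above node (root unused)
  std::vector<double> logB;      // I x J binomial loglik (no lchoose)
  std::vector<double> logBeta;    // J
  std::vector<double> cond;       // J, log P(lambda=1 | x_r)
  esr::LinDist rootdist;
  std::vector<double> xsc, tsc;   // proposal half-widths per node
  std::vector<double> tssc;       // half-widths of the single-tau wedge moves
  std::vector<double> tsacc, tstry;
  double musc = 0.1, nusc = 0.3;
  std::vector<double> xacc, xtry;
  double muacc = 0, mutry = 0, nuacc = 0, nutry = 0;
  std::vector<double> xbar;       // running sum of x over retained draws
};

struct Engine {
  int I = 0, nnode = 0, root = 0;
  std::vector<int> parent;                 // 0-based, -1 at root
  std::vector<std::vector<int>> children;
  bool condition = true, use_lik = true, update_hyper = true;
  double tau_min = 1e-4, tau_max = 10.0;
  Sys S[2];
  std::vector<double> tacc, ttry;          // joint tau blocks per node

  static double runi() { return unif_rand(); }

  static double reflect(double v, double lo, double hi) {
    double w = hi - lo;
    for (int it = 0; it < 64 && (v < lo || v > hi); ++it) {
      if (v < lo) v = 2.0 * lo - v;
      if (v > hi) v = 2.0 * hi - v;
    }
    if (v < lo) v = lo; else if (v > hi) v = hi;
    (void)w;
    return v;
  }

  double lbinom(double yv, double nv, double xv) const {
    if (nv <= 0.0) return 0.0;
    if (xv <= 0.0) return yv == 0.0 ? 0.0 : -INFINITY;
    if (xv >= 1.0) return yv == nv ? 0.0 : -INFINITY;
    return yv * std::log(xv) + (nv - yv) * std::log1p(-xv);
  }

  static double lbeta_dens(double xv, double a, double b) {
    if (xv <= 0.0 || xv >= 1.0) return -INFINITY;
    return (a - 1.0) * std::log(xv) + (b - 1.0) * std::log1p(-xv) - R::lbeta(a, b);
  }

  void refresh_rootdist(Sys &s) {
    if (!condition) return;
    s.rootdist = esr::lineage_root_distribution(parent, I, s.tau, s.nmaxleaf);
  }

  // conditioning term: the lumped state space only resolves frequencies to
  // within the atom width, so P(lambda=1 | x_r) is evaluated at x_r clamped
  // into [atom_w, 1-atom_w]; this also keeps the 1/P reward bounded
  static double log_cond(const esr::LinDist &d, double x, double atom_w) {
    if (x < atom_w) x = atom_w;
    if (x > 1.0 - atom_w) x = 1.0 - atom_w;
    return esr::log_prob_poly(d, x);
  }

  void refresh_caches(Sys &s) {
    for (int v = 0; v < nnode; ++v) {
      if (v == root) continue;
      double tv = s.tau[v];
      for (int j = 0; j < s.J; ++j)
        s.logK[v * s.J + j] =
            esr::kim_log_kernel(s.x[parent[v] * s.J + j], tv, s.x[v * s.J + j], s.atom_w);
    }
    for (int v = 0; v < I; ++v)
      for (int j = 0; j < s.J; ++j)
        s.logB[v * s.J + j] =
            use_lik ? lbinom(s.y[v * s.J + j], s.n[v * s.J + j], s.x[v * s.J + j]) : 0.0;
    double a = s.mu * s.nu, b = (1.0 - s.mu) * s.nu;
    for (int j = 0; j < s.J; ++j)
      s.logBeta[j] = lbeta_dens(s.x[root * s.J + j], a, b);
    refresh_rootdist(s);
    for (int j = 0; j < s.J; ++j)
      s.cond[j] = condition ? log_cond(s.rootdist, s.x[root * s.J + j], s.atom_w) : 0.0;
  }

  // one sweep of single-site frequency updates for one system; nodes in the
  // outer loop so memory access is contiguous in the SNP index
  void sweep_x(Sys &s) {
    std::vector<double> kidK(children[root].size() > 2 ? children[root].size() : 8);
    for (int v = 0; v < nnode; ++v) {
      for (int j = 0; j < s.J; ++j) {
        double cur = s.x[v * s.J + j];
        double prop = reflect(cur + s.xsc[v] * (2.0 * runi() - 1.0), 0.0, 1.0);
        double delta = 0.0;
        double newB = 0.0, newK = 0.0, newBeta = 0.0, newCond = 0.0;
        if (v < I && use_lik) {
          newB = lbinom(s.y[v * s.J + j], s.n[v * s.J + j], prop);
          delta += newB - s.logB[v * s.J + j];
        }
        if (v != root) {
          newK = esr::kim_log_kernel(s.x[parent[v] * s.J + j], s.tau[v], prop, s.atom_w);
          delta += newK - s.logK[v * s.J + j];
        }
        const std::vector<int> &kids = children[v];
        if (kidK.size() < kids.size()) kidK.resize(kids.size());
        for (size_t c = 0; c < kids.size(); ++c) {
          int w = kids[c];
          kidK[c] = esr::kim_log_kernel(prop, s.tau[w], s.x[w * s.J + j], s.atom_w);
          delta += kidK[c] - s.logK[w * s.J + j];
        }
        if (v == root) {
          double a = s.mu * s.nu, b = (1.0 - s.mu) * s.nu;
          newBeta = lbeta_dens(prop, a, b);
          delta += newBeta - s.logBeta[j];
          if (condition) {
            newCond = log_cond(s.rootdist, prop, s.atom_w);
            delta -= newCond - s.cond[j];
          }
        }
        s.xtry[v] += 1.0;
        if (delta >= 0.0 || std::log(runi()) < delta) {
          s.xacc[v] += 1.0;
          s.x[v * s.J + j] = prop;
          if (v < I && use_lik) s.logB[v * s.J + j] = newB;
          if (v != root) s.logK[v * s.J + j] = newK;
          for (size_t c = 0; c < kids.size(); ++c) s.logK[kids[c] * s.J + j] = kidK[c];
          if (v == root) {
            s.logBeta[j] = newBeta;
            if (condition) s.cond[j] = newCond;
          }
        }
        // independence refresh of the root frequency from its beta prior:
        // the prior cancels against the proposal density, so only the child
        // kernels and the conditioning term enter the ratio.  This move is
        // what lets the sampler reach the boundary spikes of the root
        // distribution when the fitted beta is U-shaped (alpha, beta < 1),
        // where a reflected random walk alone is effectively stuck.
        if (v == root) {
          double a = s.mu * s.nu, b = (1.0 - s.mu) * s.nu;
          double prop = R::rbeta(a, b);
          if (prop > 0.0 && prop < 1.0) {
            double delta = 0.0, newCond = 0.0;
            const std::vector<int> &kids = children[v];
            if (kidK.size() < kids.size()) kidK.resize(kids.size());
            for (size_t c = 0; c < kids.size(); ++c) {
              int w = kids[c];
              kidK[c] = esr::kim_log_kernel(prop, s.tau[w], s.x[w * s.J + j], s.atom_w);
              delta += kidK[c] - s.logK[w * s.J + j];
            }
            if (condition) {
              newCond = log_cond(s.rootdist, prop, s.atom_w);
              delta -= newCond - s.cond[j];
            }
            if (delta >= 0.0 || std::log(runi()) < delta) {
              s.x[v * s.J + j] = prop;
              s.logBeta[j] = lbeta_dens(prop, a, b);
              for (size_t c = 0; c < kids.size(); ++c) s.logK[kids[c] * s.J + j] = kidK[c];
              if (condition) s.cond[j] = newCond;
            }
          }
        }
      }
    }
  }

  void update_mu_nu(Sys &s) {
    if (!update_hyper) return;
    std::vector<double> buf(s.J);
    // mu: reflected random walk on (0,1)
    {
      double prop = reflect(s.mu + s.musc * (2.0 * runi() - 1.0), 1e-12, 1.0 - 1e-12);
      double a = prop * s.nu, b = (1.0 - prop) * s.nu;
      double delta = 0.0;
      for (int j = 0; j < s.J; ++j) {
        buf[j] = lbeta_dens(s.x[root * s.J + j], a, b);
        delta += buf[j] - s.logBeta[j];
      }
      s.mutry += 1.0;
      if (delta >= 0.0 || std::log(runi()) < delta) {
        s.muacc += 1.0;
        s.mu = prop;
        s.logBeta.swap(buf);
      }
    }
    // nu: log-scale random walk, exp(1) prior, with Jacobian
    {
      double lprop = std::log(s.nu) + s.nusc * (2.0 * runi() - 1.0);
      double prop = std::exp(lprop);
      double a = s.mu * prop, b = (1.0 - s.mu) * prop;
      double delta = -(prop - s.nu) + (lprop - std::log(s.nu));
      for (int j = 0; j < s.J; ++j) {
        buf[j] = lbeta_dens(s.x[root * s.J + j], a, b);
        delta += buf[j] - s.logBeta[j];
      }
      s.nutry += 1.0;
      if (delta >= 0.0 || std::log(runi()) < delta) {
        s.nuacc += 1.0;
        s.nu = prop;
        s.logBeta.swap(buf);
      }
    }
  }

  // joint reflected update of (tau_A, tau_X) on one branch; accepted or
  // rejected for both parameters altogether
  void update_tau(int v) {
    Sys &A = S[0], &X = S[1];
    double ta = A.tau[v], tx = X.tau[v];
    double pa = reflect(ta + A.tsc[v] * (2.0 * runi() - 1.0), tau_min, tau_max);
    double px = reflect(tx + X.tsc[v] * (2.0 * runi() - 1.0), tau_min, tau_max);
    ttry[v] += 1.0;
    // joint prior is uniform on the wedge implied by 0 < xi < 1
    if (!(pa > 9.0 * px / 16.0 && pa < 9.0 * px / 8.0)) return;
    double delta = 0.0;
    static thread_local std::vector<double> newKA, newKX, newCondA, newCondX;
    newKA.resize(A.J); newKX.resize(X.J);
    for (int j = 0; j < A.J; ++j) {
      newKA[j] = esr::kim_log_kernel(A.x[parent[v] * A.J + j], pa, A.x[v * A.J + j], A.atom_w);
      delta += newKA[j] - A.logK[v * A.J + j];
    }
    for (int j = 0; j < X.J; ++j) {
      newKX[j] = esr::kim_log_kernel(X.x[parent[v] * X.J + j], px, X.x[v * X.J + j], X.atom_w);
      delta += newKX[j] - X.logK[v * X.J + j];
    }
    esr::LinDist rdA, rdX;
    if (condition) {
      double taA = A.tau[v], taX = X.tau[v];
      A.tau[v] = pa; X.tau[v] = px;
      rdA = esr::lineage_root_distribution(parent, I, A.tau, A.nmaxleaf);
      rdX = esr::lineage_root_distribution(parent, I, X.tau, X.nmaxleaf);
      A.tau[v] = taA; X.tau[v] = taX;
      newCondA.resize(A.J); newCondX.resize(X.J);
      for (int j = 0; j < A.J; ++j) {
        newCondA[j] = log_cond(rdA, A.x[root * A.J + j], A.atom_w);
        delta -= newCondA[j] - A.cond[j];
      }
      for (int j = 0; j < X.J; ++j) {
        newCondX[j] = log_cond(rdX, X.x[root * X.J + j], X.atom_w);
        delta -= newCondX[j] - X.cond[j];
      }
    }
    if (delta >= 0.0 || std::log(runi()) < delta) {
      tacc[v] += 1.0;
      A.tau[v] = pa; X.tau[v] = px;
      for (int j = 0; j < A.J; ++j) A.logK[v * A.J + j] = newKA[j];
      for (int j = 0; j < X.J; ++j) X.logK[v * X.J + j] = newKX[j];
      if (condition) {
        A.rootdist = rdA; X.rootdist = rdX;
        A.cond.assign(newCondA.begin(), newCondA.end());
        X.cond.assign(newCondX.begin(), newCondX.end());
      }
    }
  }

  // single-coordinate wedge move: update one system's tau on branch v with
  // the other system's tau held fixed.  The conditional support interval is
  // fixed during the move, so uniform reflection into it is symmetric.
  // These moves are what mix the ratio tau_X / tau_A (hence xi); the joint
  // move above mostly shifts the common magnitude.
  void update_tau_single(int v, int sy) {
    Sys &s = S[sy];
    const Sys &o = S[1 - sy];
    double to = o.tau[v];
    double lo, hi;
    if (sy == 0) {  // tau_A given tau_X
      lo = std::max(tau_min, 9.0 * to / 16.0);
      hi = std::min(tau_max, 9.0 * to / 8.0);
    } else {        // tau_X given tau_A
      lo = std::max(tau_min, 8.0 * to / 9.0);
      hi = std::min(tau_max, 16.0 * to / 9.0);
    }
    if (hi <= lo) return;
    double prop = reflect(s.tau[v] + s.tssc[v] * (2.0 * runi() - 1.0), lo, hi);
    s.tstry[v] += 1.0;
    double delta = 0.0;
    static thread_local std::vector<double> newK, newCond;
    newK.resize(s.J);
    for (int j = 0; j < s.J; ++j) {
      newK[j] = esr::kim_log_kernel(s.x[parent[v] * s.J + j], prop,
                                    s.x[v * s.J + j], s.atom_w);
      delta += newK[j] - s.logK[v * s.J + j];
    }
    esr::LinDist rd;
    if (condition) {
      double keep = s.tau[v];
      s.tau[v] = prop;
      rd = esr::lineage_root_distribution(parent, I, s.tau, s.nmaxleaf);
      s.tau[v] = keep;
      newCond.resize(s.J);
      for (int j = 0; j < s.J; ++j) {
        newCond[j] = log_cond(rd, s.x[root * s.J + j], s.atom_w);
        delta -= newCond[j] - s.cond[j];
      }
    }
    if (delta >= 0.0 || std::log(runi()) < delta) {
      s.tsacc[v] += 1.0;
      s.tau[v] = prop;
      for (int j = 0; j < s.J; ++j) s.logK[v * s.J + j] = newK[j];
      if (condition) {
        s.rootdist = rd;
        s.cond.assign(newCond.begin(), newCond.end());
      }
    }
  }

  void iterate() {
    for (int sy = 0; sy < 2; ++sy) {
      sweep_x(S[sy]);
      update_mu_nu(S[sy]);
    }
    for (int v = 0; v < nnode; ++v)
      if (v != root) {
        update_tau(v);
        update_tau_single(v, 0);
        update_tau_single(v, 1);
      }
  }

  double deviance(const Sys &s) const {
    double sb = 0.0, sc = 0.0, lc = 0.0;
    for (int v = 0; v < I; ++v)
      for (int j = 0; j < s.J; ++j) sb += s.logB[v * s.J + j];
    for (int j = 0; j < s.J; ++j) { sc += s.cond[j]; lc += s.lchoose_sum[j]; }
    return -2.0 * (sb + lc - sc);
  }

  void reset_acc() {
    for (int sy = 0; sy < 2; ++sy) {
      std::fill(S[sy].xacc.begin(), S[sy].xacc.end(), 0.0);
      std::fill(S[sy].xtry.begin(), S[sy].xtry.end(), 0.0);
      std::fill(S[sy].tsacc.begin(), S[sy].tsacc.end(), 0.0);
      std::fill(S[sy].tstry.begin(), S[sy].tstry.end(), 0.0);
      S[sy].muacc = S[sy].mutry = S[sy].nuacc = S[sy].nutry = 0.0;
    }
    std::fill(tacc.begin(), tacc.end(), 0.0);
    std::fill(ttry.begin(), ttry.end(), 0.0);
  }

  static double adapt_scale(double sc, double rate, double lo, double hi,
                            double factor, double smin, double smax) {
    if (rate > hi) sc *= factor;
    else if (rate < lo) sc /= factor;
    if (sc < smin) sc = smin;
    if (sc > smax) sc = smax;
    return sc;
  }

  void pilot(int n_pilot, int pilot_length, double lo, double hi, double factor,
             bool verbose) {
    for (int p = 0; p < n_pilot; ++p) {
      reset_acc();
      for (int it = 0; it < pilot_length; ++it) iterate();
      for (int sy = 0; sy < 2; ++sy) {
        Sys &s = S[sy];
        for (int v = 0; v < nnode; ++v) {
          double r = s.xtry[v] > 0 ? s.xacc[v] / s.xtry[v] : 0.0;
          s.xsc[v] = adapt_scale(s.xsc[v], r, lo, hi, factor, 1e-5, 1.0);
        }
        double rmu = s.mutry > 0 ? s.muacc / s.mutry : 0.0;
        s.musc = adapt_scale(s.musc, rmu, lo, hi, factor, 1e-5, 1.0);
        double rnu = s.nutry > 0 ? s.nuacc / s.nutry : 0.0;
        s.nusc = adapt_scale(s.nusc, rnu, lo, hi, factor, 1e-5, 5.0);
        for (int v = 0; v < nnode; ++v) {
          if (v == root) continue;
          double rs = s.tstry[v] > 0 ? s.tsacc[v] / s.tstry[v] : 0.0;
          s.tssc[v] = adapt_scale(s.tssc[v], rs, lo, hi, factor, 1e-7, tau_max);
        }
      }
      for (int v = 0; v < nnode; ++v) {
        if (v == root) continue;
        double r = ttry[v] > 0 ? tacc[v] / ttry[v] : 0.0;
        S[0].tsc[v] = adapt_scale(S[0].tsc[v], r, lo, hi, factor, 1e-7, tau_max);
        S[1].tsc[v] = adapt_scale(S[1].tsc[v], r, lo, hi, factor, 1e-7, tau_max);
      }
      if (verbose)
        REprintf("pilot %d/%d done (tau acc branch 0: %.2f)\n", p + 1, n_pilot,
                 ttry[0] > 0 ? tacc[0] / ttry[0] : 0.0);
      Rcpp::checkUserInterrupt();
    }
  }
};

void init_sys(Sys &s, const IntegerMatrix &y, const IntegerMatrix &n,
              const NumericMatrix &x0, const NumericVector &tau0,
              double mu0, double nu0, double atom_w, int nnode, int I) {
  s.J = y.ncol();
  s.y.resize((size_t)I * s.J);
  s.n.resize((size_t)I * s.J);
  s.lchoose_sum.assign(s.J, 0.0);
  s.nmaxleaf.assign(I, 0);
  for (int v = 0; v < I; ++v)
    for (int j = 0; j < s.J; ++j) {
      s.y[v * s.J + j] = y(v, j);
      s.n[v * s.J + j] = n(v, j);
      s.lchoose_sum[j] += R::lchoose(n(v, j), y(v, j));
      if (n(v, j) > s.nmaxleaf[v]) s.nmaxleaf[v] = n(v, j);
    }
  s.atom_w = atom_w;
  s.x.resize((size_t)nnode * s.J);
  for (int v = 0; v < nnode; ++v)
    for (int j = 0; j < s.J; ++j) s.x[v * s.J + j] = x0(v, j);
  s.tau.assign(tau0.begin(), tau0.end());
  s.mu = mu0; s.nu = nu0;
  s.logK.assign((size_t)nnode * s.J, 0.0);
  s.logB.assign((size_t)I * s.J, 0.0);
  s.logBeta.assign(s.J, 0.0);
  s.cond.assign(s.J, 0.0);
  s.xacc.assign(nnode, 0.0);
  s.xtry.assign(nnode, 0.0);
  s.tssc.assign(nnode, 0.02);
  s.tsacc.assign(nnode, 0.0);
  s.tstry.assign(nnode, 0.0);
  s.xbar.assign((size_t)nnode * s.J, 0.0);
}

} // namespace

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerMatrix y_a, IntegerMatrix n_a, IntegerMatrix y_x,
                   IntegerMatrix n_x, IntegerVector parent0, int nleaf,
                   List children0, NumericMatrix x0_a, NumericMatrix x0_x,
                   NumericVector tau0_a, NumericVector tau0_x,
                   NumericVector hyper0, NumericVector atom_w, List scales,
                   List control) {
  Engine E;
  E.I = nleaf;
  E.nnode = parent0.size();
  E.parent.assign(parent0.begin(), parent0.end());
  E.children.resize(E.nnode);
  for (int v = 0; v < E.nnode; ++v) {
    IntegerVector kv = children0[v];
    E.children[v].assign(kv.begin(), kv.end());
    if (E.parent[v] < 0) E.root = v;
  }
  E.condition = as<bool>(control["condition"]);
  E.use_lik = as<bool>(control["use_likelihood"]);
  E.update_hyper = as<bool>(control["update_hyper"]);
  E.tau_min = as<double>(control["tau_min"]);
  E.tau_max = as<double>(control["tau_max"]);
  bool verbose = as<bool>(control["verbose"]);
  bool record_root = as<bool>(control["record_root"]);

  init_sys(E.S[0], y_a, n_a, x0_a, tau0_a, hyper0[0], hyper0[1], atom_w[0], E.nnode, E.I);
  init_sys(E.S[1], y_x, n_x, x0_x, tau0_x, hyper0[2], hyper0[3], atom_w[1], E.nnode, E.I);
  E.S[0].xsc = as<std::vector<double>>(scales["x_a"]);
  E.S[1].xsc = as<std::vector<double>>(scales["x_x"]);
  E.S[0].tsc = as<std::vector<double>>(scales["tau_a"]);
  E.S[1].tsc = as<std::vector<double>>(scales["tau_x"]);
  E.S[0].musc = as<NumericVector>(scales["mu"])[0];
  E.S[1].musc = as<NumericVector>(scales["mu"])[1];
  E.S[0].nusc = as<NumericVector>(scales["nu"])[0];
  E.S[1].nusc = as<NumericVector>(scales["nu"])[1];
  E.tacc.assign(E.nnode, 0.0);
  E.ttry.assign(E.nnode, 0.0);

  E.refresh_caches(E.S[0]);
  E.refresh_caches(E.S[1]);

  int n_pilot = as<int>(control["n_pilot"]);
  int pilot_length = as<int>(control["pilot_length"]);
  int burnin = as<int>(control["burnin"]);
  int chain_length = as<int>(control["chain_length"]);
  int thin = as<int>(control["thin"]);
  double acc_lo = as<double>(control["acc_lo"]);
  double acc_hi = as<double>(control["acc_hi"]);
  double adapt_factor = as<double>(control["adapt_factor"]);

  E.pilot(n_pilot, pilot_length, acc_lo, acc_hi, adapt_factor, verbose);

  for (int it = 0; it < burnin; ++it) {
    E.iterate();
    if (verbose && (it + 1) % 1000 == 0) REprintf("burn-in %d/%d\n", it + 1, burnin);
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  E.reset_acc();
  int ndraw = chain_length / thin;
  int nbr = E.nnode - 1;
  int ncol = 2 * nbr + 4 + 3;  // tau_A, tau_X, mu/nu per system, deviances
  NumericMatrix draws(ndraw, ncol);
  NumericMatrix rootdraws_a, rootdraws_x;
  if (record_root) {
    rootdraws_a = NumericMatrix(ndraw, E.S[0].J);
    rootdraws_x = NumericMatrix(ndraw, E.S[1].J);
  }
  int row = 0;
  for (int it = 0; it < chain_length; ++it) {
    E.iterate();
    if ((it + 1) % thin == 0 && row < ndraw) {
      int c = 0;
      for (int v = 0; v < E.nnode; ++v)
        if (v != E.root) draws(row, c++) = E.S[0].tau[v];
      for (int v = 0; v < E.nnode; ++v)
        if (v != E.root) draws(row, c++) = E.S[1].tau[v];
      draws(row, c++) = E.S[0].mu; draws(row, c++) = E.S[0].nu;
      draws(row, c++) = E.S[1].mu; draws(row, c++) = E.S[1].nu;
      double dA = E.deviance(E.S[0]), dX = E.deviance(E.S[1]);
      draws(row, c++) = dA; draws(row, c++) = dX; draws(row, c++) = dA + dX;
      for (int sy = 0; sy < 2; ++sy) {
        Sys &s = E.S[sy];
        for (size_t k = 0; k < s.x.size(); ++k) s.xbar[k] += s.x[k];
      }
      if (record_root) {
        for (int j = 0; j < E.S[0].J; ++j) rootdraws_a(row, j) = E.S[0].x[E.root * E.S[0].J + j];
        for (int j = 0; j < E.S[1].J; ++j) rootdraws_x(row, j) = E.S[1].x[E.root * E.S[1].J + j];
      }
      ++row;
    }
    if (verbose && (it + 1) % 1000 == 0) REprintf("sampling %d/%d\n", it + 1, chain_length);
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  auto xbar_mat = [&](int sy) {
    Sys &s = E.S[sy];
    NumericMatrix m(E.nnode, s.J);
    double denom = row > 0 ? (double)row : 1.0;
    for (int v = 0; v < E.nnode; ++v)
      for (int j = 0; j < s.J; ++j) m(v, j) = s.xbar[v * s.J + j] / denom;
    return m;
  };
  auto accvec = [&](int sy) {
    Sys &s = E.S[sy];
    NumericVector a(E.nnode);
    for (int v = 0; v < E.nnode; ++v) a[v] = s.xtry[v] > 0 ? s.xacc[v] / s.xtry[v] : NA_REAL;
    return a;
  };
  NumericVector tau_acc(E.nnode);
  for (int v = 0; v < E.nnode; ++v)
    tau_acc[v] = E.ttry[v] > 0 ? E.tacc[v] / E.ttry[v] : NA_REAL;
  auto ts_acc = [&](int sy) {
    Sys &s = E.S[sy];
    NumericVector a(E.nnode);
    for (int v = 0; v < E.nnode; ++v)
      a[v] = s.tstry[v] > 0 ? s.tsacc[v] / s.tstry[v] : NA_REAL;
    return a;
  };

  List out = List::create(
      _["draws"] = draws,
      _["xbar_a"] = xbar_mat(0), _["xbar_x"] = xbar_mat(1),
      _["acc_x_a"] = accvec(0), _["acc_x_x"] = accvec(1),
      _["acc_tau"] = tau_acc,
      _["acc_tau_single_a"] = ts_acc(0), _["acc_tau_single_x"] = ts_acc(1),
      _["acc_mu"] = NumericVector::create(
          E.S[0].mutry > 0 ? E.S[0].muacc / E.S[0].mutry : NA_REAL,
          E.S[1].mutry > 0 ? E.S[1].muacc / E.S[1].mutry : NA_REAL),
      _["acc_nu"] = NumericVector::create(
          E.S[0].nutry > 0 ? E.S[0].nuacc / E.S[0].nutry : NA_REAL,
          E.S[1].nutry > 0 ? E.S[1].nuacc / E.S[1].nutry : NA_REAL),
      _["scales"] = List::create(
          _["x_a"] = E.S[0].xsc, _["x_x"] = E.S[1].xsc,
          _["tau_a"] = E.S[0].tsc, _["tau_x"] = E.S[1].tsc,
          _["mu"] = NumericVector::create(E.S[0].musc, E.S[1].musc),
          _["nu"] = NumericVector::create(E.S[0].nusc, E.S[1].nusc)));
  if (record_root) {
    out["root_draws_a"] = rootdraws_a;
    out["root_draws_x"] = rootdraws_x;
  }
  return out;
}
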