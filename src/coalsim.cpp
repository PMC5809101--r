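#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Generation-by-generation backward simulator of unlinked bi-allelic loci on a
// population tree with separate female/male census sizes per branch, optional
// instantaneous size changes, and sex-specific migration between one pair of
// leaf populations.  Lineages pick parents individual-by-individual each
// generation (no pedigree is stored); autosomal lineages pick a female or male
// parent with probability 1/2, X-linked lineages in a female do likewise while
// X lineages in a male always pick the mother.  Once every lineage has entered
// the root population, waiting times to the next coalescence are drawn
// geometrically at the pairwise rate 1/(2 Ne) implied by Wright's effective
// sizes whenever that is an accurate aggregation (large root sizes), falling
// back to explicit per-generation resolution otherwise.  Each locus keeps
// exactly one mutation, placed uniformly on the realised genealogy.

namespace {

struct Lineage {
  int pop;        // current population (tree node id, 0-based)
  bool male;      // carrier sex (X only; ignored for autosomes)
  int gnode;      // genealogy node id
};

struct Regime {
  const std::vector<double> *t;
  const std::vector<double> *nf;
  const std::vector<double> *nm;
  void at(double time, double &Nf, double &Nm) const {
    size_t k = 0;
    for (size_t i = 0; i < t->size(); ++i)
      if ((*t)[i] <= time) k = i;
    Nf = (*nf)[k];
    Nm = (*nm)[k];
  }
};

inline double ne_sys(double Nf, double Nm, bool xlinked) {
  if (xlinked) return 9.0 * Nf * Nm / (2.0 * Nf + 4.0 * Nm);
  return 4.0 * Nf * Nm / (Nf + Nm);
}

} // namespace

// [[Rcpp::export(name = ".coalsim_cpp")]]
List coalsim_cpp(IntegerVector parent0, int nleaf, NumericVector node_time,
                 List sz_t, List sz_nf, List sz_nm,
                 IntegerVector samp_f, IntegerVector samp_m, bool xlinked,
                 int J, double mu, IntegerVector mig_pair, double mig_f,
                 double mig_m, int max_attempts, bool collect_times) {
  int nnode = parent0.size();
  int root = 0;
  std::vector<int> parent(parent0.begin(), parent0.end());
  for (int v = 0; v < nnode; ++v) if (parent[v] < 0) root = v;

  std::vector<std::vector<double>> szt(nnode), szf(nnode), szm(nnode);
  for (int v = 0; v < nnode; ++v) {
    szt[v] = as<std::vector<double>>(sz_t[v]);
    szf[v] = as<std::vector<double>>(sz_nf[v]);
    szm[v] = as<std::vector<double>>(sz_nm[v]);
  }

  // per-leaf sampled gene counts for this genetic system
  std::vector<int> ngenes(nleaf);
  int L = 0;
  for (int v = 0; v < nleaf; ++v) {
    ngenes[v] = xlinked ? 2 * samp_f[v] + samp_m[v] : 2 * (samp_f[v] + samp_m[v]);
    L += ngenes[v];
  }
  int migA = mig_pair[0], migB = mig_pair[1];
  double mig_end = -1.0;
  if (migA >= 0) mig_end = std::min(node_time[parent[migA]], node_time[parent[migB]]);

  IntegerMatrix ymat(nleaf, J);
  NumericVector tmrca(collect_times ? J : 0), tlen(collect_times ? J : 0);
  long attempts = 0;

  // genealogy buffers
  std::vector<double> gtime;
  std::vector<int> gpar;
  std::vector<int> leaf_pop(L);
  std::vector<Lineage> lin;
  std::vector<uint64_t> keys;
  std::vector<int> ord;

  // stamped direct-address table over parental gene copies: O(k) collision
  // detection per generation without sorting.  Layout per population: female
  // copies first (2 Nf_max slots), then male copies (2 Nm_max slots).
  std::vector<double> nfmax(nnode, 0.0), nmmax(nnode, 0.0);
  for (int p = 0; p < nnode; ++p) {
    for (double v : szf[p]) nfmax[p] = std::max(nfmax[p], v);
    for (double v : szm[p]) nmmax[p] = std::max(nmmax[p], v);
  }
  std::vector<size_t> cbase(nnode + 1, 0);
  for (int p = 0; p < nnode; ++p)
    cbase[p + 1] = cbase[p] + 2 * (size_t)nfmax[p] + 2 * (size_t)nmmax[p];
  bool use_stamp = cbase[nnode] <= ((size_t)1 << 26);
  std::vector<uint32_t> stamp;
  std::vector<int> owner;
  if (use_stamp) {
    stamp.assign(cbase[nnode], 0u);
    owner.assign(cbase[nnode], 0);
  }
  uint32_t stamp_gen = 0;

  for (int locus = 0; locus < J; ++locus) {
    bool done = false;
    int tries = 0;
    while (!done) {
      if (++tries > max_attempts)
        stop("locus rejected more than max_attempts times; check mutation rate / demography");
      ++attempts;
      // initialise sample
      gtime.assign(L, 0.0);
      gpar.assign(L, -1);
      lin.clear();
      int id = 0;
      for (int v = 0; v < nleaf; ++v) {
        for (int f = 0; f < samp_f[v]; ++f)
          for (int c = 0; c < 2; ++c) { lin.push_back({v, false, id}); leaf_pop[id] = v; ++id; }
        int male_genes = xlinked ? samp_m[v] : 2 * samp_m[v];
        for (int g = 0; g < male_genes; ++g) { lin.push_back({v, true, id}); leaf_pop[id] = v; ++id; }
      }
      double t = 0.0;
      // chronological per-generation phase until everything sits in the root
      while (true) {
        // merge populations whose ancestral node starts at time t
        for (auto &ln : lin) {
          int p = ln.pop;
          while (parent[p] >= 0 && node_time[parent[p]] <= t) p = parent[p];
          ln.pop = p;
        }
        bool all_root = true;
        for (auto &ln : lin) if (ln.pop != root) { all_root = false; break; }
        if (all_root || lin.size() == 1) break;

        // quiet-phase shortcut: when coalescence is rare everywhere and no
        // migration is active, jump geometrically to the next event or to the
        // next demographic boundary instead of stepping every generation
        bool mig_on_now = migA >= 0 && t < mig_end;
        if (!mig_on_now) {
          std::vector<int> kpop(nnode, 0);
          for (auto &ln : lin) kpop[ln.pop] += 1;
          double R = 0.0;
          std::vector<double> rate(nnode, 0.0);
          for (int p = 0; p < nnode; ++p) {
            if (kpop[p] < 2) continue;
            double Nf, Nm;
            Regime rg{&szt[p], &szf[p], &szm[p]};
            rg.at(t + 1.0, Nf, Nm);
            rate[p] = (double)kpop[p] * (kpop[p] - 1) / 2.0 /
                      (2.0 * ne_sys(Nf, Nm, xlinked));
            R += rate[p];
          }
          if (R < 0.02) {
            // next demographic boundary: node splits, size changes, migration
            double Tb = std::numeric_limits<double>::infinity();
            for (int m = nleaf; m < nnode; ++m)
              if (node_time[m] > t) Tb = std::min(Tb, (double)node_time[m]);
            for (int p = 0; p < nnode; ++p)
              if (kpop[p] > 0)
                for (double te : szt[p])
                  if (te > t + 1.0) Tb = std::min(Tb, te - 1.0);
            if (migA >= 0 && mig_end > t) Tb = std::min(Tb, mig_end);
            double dt;
            if (R <= 0.0) dt = Tb - t;
            else {
              dt = std::ceil(std::log(unif_rand()) / std::log1p(-R));
              if (dt < 1.0) dt = 1.0;
            }
            if (R <= 0.0 || t + dt >= Tb) { t = Tb; continue; }
            t += dt;
            // pick the population in proportion to its pairwise rate
            double u = unif_rand() * R, acc2 = 0.0;
            int pop = -1;
            for (int p = 0; p < nnode; ++p) {
              acc2 += rate[p];
              if (u <= acc2) { pop = p; break; }
            }
            if (pop < 0) for (int p = nnode - 1; p >= 0; --p) if (rate[p] > 0) { pop = p; break; }
            // merge a uniform pair within that population
            std::vector<int> idxs;
            for (size_t q = 0; q < lin.size(); ++q) if (lin[q].pop == pop) idxs.push_back((int)q);
            size_t kk = idxs.size();
            size_t a = (size_t)std::floor(unif_rand() * kk);
            if (a >= kk) a = kk - 1;
            size_t b = (size_t)std::floor(unif_rand() * (kk - 1));
            if (b >= kk - 1) b = kk - 2;
            if (b >= a) ++b;
            int ia = idxs[a], ib = idxs[b];
            int nn = (int)gtime.size();
            gtime.push_back(t);
            gpar.push_back(-1);
            gpar[lin[ia].gnode] = nn;
            gpar[lin[ib].gnode] = nn;
            lin[ia].gnode = nn;
            lin.erase(lin.begin() + ib);
            // carrier sexes relax to the stationary 2/3-female split
            if (xlinked)
              for (auto &ln : lin) ln.male = unif_rand() < (1.0 / 3.0);
            continue;
          }
        }

        // one generation backward: assign parents, detect collisions.
        // A single uniform draw per lineage yields the parent's sex and gene
        // copy: the residual after the sex choice stays uniform.
        bool mig_on = migA >= 0 && t < mig_end;
        if (use_stamp) {
          ++stamp_gen;
          if (stamp_gen == 0u) {  // counter wrapped: clear and restart
            std::fill(stamp.begin(), stamp.end(), 0u);
            stamp_gen = 1u;
          }
          size_t w = 0;
          for (size_t i = 0; i < lin.size(); ++i) {
            Lineage ln = lin[i];
            double u = unif_rand();
            bool par_male;
            double v;
            if (!xlinked || !ln.male) {
              par_male = u >= 0.5;
              v = par_male ? 2.0 * (u - 0.5) : 2.0 * u;
            } else {
              par_male = false;  // X in a male always comes from the mother
              v = u;
            }
            if (mig_on && (ln.pop == migA || ln.pop == migB)) {
              double m = par_male ? mig_m : mig_f;
              if (m > 0.0 && unif_rand() < m) ln.pop = (ln.pop == migA) ? migB : migA;
            }
            double Nf, Nm;
            Regime rg{&szt[ln.pop], &szf[ln.pop], &szm[ln.pop]};
            rg.at(t + 1.0, Nf, Nm);
            // number of parental gene copies on the chosen side
            double G = par_male ? (xlinked ? Nm : 2.0 * Nm) : 2.0 * Nf;
            size_t c = (size_t)(v * G);
            if (c >= (size_t)G) c = (size_t)G - 1;
            size_t key = cbase[ln.pop] + (par_male ? 2 * (size_t)nfmax[ln.pop] : 0) + c;
            ln.male = par_male;
            if (stamp[key] != stamp_gen) {
              stamp[key] = stamp_gen;
              owner[key] = (int)w;
              lin[w++] = ln;
            } else {
              Lineage &host = lin[owner[key]];
              if (gtime[host.gnode] == t + 1.0) {
                gpar[ln.gnode] = host.gnode;  // third+ lineage in the same copy
              } else {
                int nn = (int)gtime.size();
                gtime.push_back(t + 1.0);
                gpar.push_back(-1);
                gpar[host.gnode] = nn;
                gpar[ln.gnode] = nn;
                host.gnode = nn;
              }
            }
          }
          lin.resize(w);
          t += 1.0;
          continue;
        }
        // fallback for very large census layouts: sort-based grouping
        keys.resize(lin.size());
        for (size_t i = 0; i < lin.size(); ++i) {
          Lineage &ln = lin[i];
          bool par_male;
          if (!xlinked) par_male = unif_rand() < 0.5;
          else par_male = ln.male ? false : (unif_rand() < 0.5);
          int pop = ln.pop;
          if (mig_on && (pop == migA || pop == migB)) {
            double m = par_male ? mig_m : mig_f;
            if (m > 0.0 && unif_rand() < m) pop = (pop == migA) ? migB : migA;
          }
          double Nf, Nm;
          Regime rg{&szt[pop], &szf[pop], &szm[pop]};
          rg.at(t + 1.0, Nf, Nm);
          double N = par_male ? Nm : Nf;
          uint64_t idx = (uint64_t)std::floor(unif_rand() * N);
          if (idx >= (uint64_t)N) idx = (uint64_t)N - 1;
          int ncopy = (!xlinked || !par_male) ? 2 : 1;
          uint64_t copy = ncopy == 2 ? (unif_rand() < 0.5 ? 0 : 1) : 0;
          ln.pop = pop;
          ln.male = par_male;
          keys[i] = ((((uint64_t)pop * 2 + (par_male ? 1 : 0)) << 40) | (idx << 1)) | copy;
        }
        // group identical parent copies -> coalescence at generation t+1
        ord.resize(lin.size());
        for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return keys[a] < keys[b]; });
        std::vector<Lineage> nxt;
        nxt.reserve(lin.size());
        size_t i = 0;
        while (i < ord.size()) {
          size_t jx = i + 1;
          while (jx < ord.size() && keys[ord[jx]] == keys[ord[i]]) ++jx;
          if (jx == i + 1) nxt.push_back(lin[ord[i]]);
          else {
            int nn = (int)gtime.size();
            gtime.push_back(t + 1.0);
            gpar.push_back(-1);
            for (size_t q = i; q < jx; ++q) gpar[lin[ord[q]].gnode] = nn;
            Lineage merged = lin[ord[i]];
            merged.gnode = nn;
            nxt.push_back(merged);
          }
          i = jx;
        }
        lin.swap(nxt);
        t += 1.0;
      }

      // root phase
      double Nf, Nm;
      Regime rg{&szt[root], &szf[root], &szm[root]};
      while (lin.size() > 1) {
        rg.at(t + 1.0, Nf, Nm);
        double Ne = ne_sys(Nf, Nm, xlinked);
        size_t k = lin.size();
        double pk = (double)k * (k - 1) / 2.0 / (2.0 * Ne);
        if (pk < 0.05) {
          // geometric waiting time at the aggregated pairwise rate
          double u = unif_rand();
          double gens = std::ceil(std::log(u) / std::log1p(-pk));
          if (gens < 1.0) gens = 1.0;
          t += gens;
          size_t a = (size_t)std::floor(unif_rand() * k);
          if (a >= k) a = k - 1;
          size_t b = (size_t)std::floor(unif_rand() * (k - 1));
          if (b >= k - 1) b = k - 2;
          if (b >= a) ++b;
          int nn = (int)gtime.size();
          gtime.push_back(t);
          gpar.push_back(-1);
          gpar[lin[a].gnode] = nn;
          gpar[lin[b].gnode] = nn;
          Lineage merged = lin[a];
          merged.gnode = nn;
          lin[std::min(a, b)] = merged;
          lin.erase(lin.begin() + std::max(a, b));
        } else {
          // explicit generation: same mechanics as the branch phase
          keys.resize(lin.size());
          for (size_t q = 0; q < lin.size(); ++q) {
            Lineage &ln = lin[q];
            bool par_male = !xlinked ? (unif_rand() < 0.5)
                                     : (ln.male ? false : (unif_rand() < 0.5));
            double N = par_male ? Nm : Nf;
            uint64_t idx = (uint64_t)std::floor(unif_rand() * N);
            if (idx >= (uint64_t)N) idx = (uint64_t)N - 1;
            int ncopy = (!xlinked || !par_male) ? 2 : 1;
            uint64_t copy = ncopy == 2 ? (unif_rand() < 0.5 ? 0 : 1) : 0;
            ln.male = par_male;
            keys[q] = (((uint64_t)(par_male ? 1 : 0) << 40) | (idx << 1)) | copy;
          }
          ord.resize(lin.size());
          for (size_t q = 0; q < ord.size(); ++q) ord[q] = (int)q;
          std::sort(ord.begin(), ord.end(),
                    [&](int a, int b) { return keys[a] < keys[b]; });
          std::vector<Lineage> nxt;
          size_t q = 0;
          while (q < ord.size()) {
            size_t jx = q + 1;
            while (jx < ord.size() && keys[ord[jx]] == keys[ord[q]]) ++jx;
            if (jx == q + 1) nxt.push_back(lin[ord[q]]);
            else {
              int nn = (int)gtime.size();
              gtime.push_back(t + 1.0);
              gpar.push_back(-1);
              for (size_t w = q; w < jx; ++w) gpar[lin[ord[w]].gnode] = nn;
              Lineage merged = lin[ord[q]];
              merged.gnode = nn;
              nxt.push_back(merged);
            }
            q = jx;
          }
          lin.swap(nxt);
          t += 1.0;
        }
      }

      // single-mutation rejection sampling on the realised genealogy
      double Ltot = 0.0;
      int nG = (int)gtime.size();
      for (int v = 0; v < nG; ++v)
        if (gpar[v] >= 0) Ltot += gtime[gpar[v]] - gtime[v];
      if (collect_times) {
        tmrca[locus] = gtime.back();
        tlen[locus] = Ltot;
        done = true;
        continue;
      }
      int nmut = (int)R::rpois(mu * Ltot);
      if (nmut != 1) continue;
      double target = unif_rand() * Ltot, acc = 0.0;
      int mnode = -1;
      for (int v = 0; v < nG; ++v) {
        if (gpar[v] < 0) continue;
        acc += gtime[gpar[v]] - gtime[v];
        if (acc >= target) { mnode = v; break; }
      }
      if (mnode < 0) continue;
      // derived leaves under mnode
      std::vector<std::vector<int>> gchild(nG);
      for (int v = 0; v < nG; ++v) if (gpar[v] >= 0) gchild[gpar[v]].push_back(v);
      std::vector<int> stack{mnode};
      std::vector<int> derived(nleaf, 0);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < L) derived[leaf_pop[v]] += 1;
        for (int c : gchild[v]) stack.push_back(c);
      }
      bool ref_is_derived = unif_rand() < 0.5;
      for (int v = 0; v < nleaf; ++v)
        ymat(v, locus) = ref_is_derived ? derived[v] : ngenes[v] - derived[v];
      done = true;
    }
    if ((locus + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["y"] = ymat,
                          _["n"] = IntegerVector(ngenes.begin(), ngenes.end()),
                          _["attempts"] = (double)attempts);
  if (collect_times) { out["tmrca"] = tmrca; out["tlen"] = tlen; }
  return out;
}
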