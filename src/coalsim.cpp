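#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Structured-coalescent engine shared by all simulation entry points.
//
// Demes are indexed 0..nd-1.  Backward-time divergence events are supplied
// as (time, a, b, dest): at `time` all lineages in demes a and b move into
// deme dest.  Epoch e spans [t_{e}, t_{e+1}) with t_0 = 0; each epoch has
// its own nd x nd backward migration-rate matrix (rate per lineage per
// generation of moving from row deme to column deme).  Coalescence within
// a deme of diploid size N proceeds at rate k(k-1)/(4N) per generation.
// Uses R's RNG throughout so set.seed() controls reproducibility.

namespace {

struct Lineage {
  uint64_t mask;   // tips below this lineage (<= 64 tips)
  double btime;    // time this lineage was created (tip: 0)
  int deme;
  int node;        // node id (tips 0..n-1, internals n, n+1, ...)
};

struct Branch {
  uint64_t mask;
  double len;
};

struct CoalRec {           // one coalescence, for topology output
  int parent, c1, c2;
  double time;
};

struct EngineArgs {
  int nd;
  std::vector<double> etimes;          // ne event times, ascending
  std::vector<int> ea, eb, edest;
  std::vector<double> sizes;           // diploid Ne per deme
  std::vector<std::vector<double>> mig;    // per epoch, nd*nd
  std::vector<std::vector<double>> migrow; // per epoch, row sums
  std::vector<int> samples;            // gene copies per deme
  int ntip;
};

EngineArgs unpack(const NumericVector &event_times, const IntegerMatrix &events,
                  const NumericVector &sizes, const NumericVector &mig,
                  const IntegerVector &samples) {
  EngineArgs A;
  A.nd = sizes.size();
  int ne = event_times.size();
  if (events.nrow() != ne || events.ncol() != 3)
    stop("events must be ne x 3 (a, b, dest), matching event_times");
  for (int e = 0; e < ne; ++e) {
    A.etimes.push_back(event_times[e]);
    A.ea.push_back(events(e, 0));
    A.eb.push_back(events(e, 1));
    A.edest.push_back(events(e, 2));
    if (e > 0 && event_times[e] < event_times[e - 1])
      stop("event times must be non-decreasing");
  }
  for (int d = 0; d < A.nd; ++d) A.sizes.push_back(sizes[d]);
  int nep = ne + 1;
  if ((int)mig.size() != nep * A.nd * A.nd)
    stop("migration array must have (n_events+1)*nd*nd entries");
  A.mig.resize(nep);
  A.migrow.resize(nep);
  for (int ep = 0; ep < nep; ++ep) {
    A.mig[ep].assign(mig.begin() + (R_xlen_t)ep * A.nd * A.nd,
                     mig.begin() + (R_xlen_t)(ep + 1) * A.nd * A.nd);
    A.migrow[ep].assign(A.nd, 0.0);
    for (int i = 0; i < A.nd; ++i)
      for (int j = 0; j < A.nd; ++j)
        A.migrow[ep][i] += A.mig[ep][i * A.nd + j];
  }
  A.ntip = 0;
  for (int d = 0; d < (int)samples.size(); ++d) A.ntip += samples[d];
  if ((int)samples.size() != A.nd) stop("samples must have one entry per deme");
  if (A.ntip < 2) stop("need at least two sampled gene copies");
  if (A.ntip > 64) stop("at most 64 sampled gene copies supported");
  for (int d = 0; d < A.nd; ++d) A.samples.push_back(samples[d]);
  return A;
}

// Simulate one genealogy; fills `branches` (every edge below the root) and,
// if `recs` is non-null, the coalescence records for topology output.
void sim_tree(const EngineArgs &A, std::vector<Branch> &branches,
              std::vector<CoalRec> *recs) {
  branches.clear();
  std::vector<Lineage> act;
  act.reserve(A.ntip);
  std::vector<int> k(A.nd, 0);
  int tip = 0;
  for (int d = 0; d < A.nd; ++d)
    for (int i = 0; i < A.samples[d]; ++i) {
      Lineage L;
      L.mask = (uint64_t)1 << tip;
      L.btime = 0.0;
      L.deme = d;
      L.node = tip;
      act.push_back(L);
      ++tip;
      ++k[d];
    }
  int nextnode = A.ntip;
  double t = 0.0;
  int epoch = 0;
  const int ne = (int)A.etimes.size();

  auto apply_events = [&](double upto) {
    while (epoch < ne && A.etimes[epoch] <= upto + 1e-12) {
      int a = A.ea[epoch], b = A.eb[epoch], dd = A.edest[epoch];
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == a || act[i].deme == b) {
          --k[act[i].deme];
          act[i].deme = dd;
          ++k[dd];
        }
      ++epoch;
    }
  };

  while ((int)act.size() > 1) {
    // event rates in the current epoch
    double tot = 0.0;
    std::vector<double> crate(A.nd, 0.0), mrate(A.nd, 0.0);
    for (int d = 0; d < A.nd; ++d) {
      if (k[d] >= 2) crate[d] = k[d] * (k[d] - 1) / (4.0 * A.sizes[d]);
      if (k[d] >= 1) mrate[d] = k[d] * A.migrow[epoch][d];
      tot += crate[d] + mrate[d];
    }
    double tnext = (epoch < ne) ? A.etimes[epoch] : R_PosInf;
    if (tot <= 0.0) {
      if (!R_finite(tnext))
        stop("coalescent cannot complete: isolated lineages with no events left");
      t = tnext;
      apply_events(t);
      continue;
    }
    double dt = R::rexp(1.0 / tot);
    if (t + dt >= tnext) {
      t = tnext;
      apply_events(t);
      continue;
    }
    t += dt;
    double u = unif_rand() * tot;
    int d = 0;
    bool coal = false;
    for (d = 0; d < A.nd; ++d) {
      if (u < crate[d]) { coal = true; break; }
      u -= crate[d];
      if (u < mrate[d]) { coal = false; break; }
      u -= mrate[d];
    }
    if (d == A.nd) d = A.nd - 1;  // numerical guard
    if (coal) {
      // choose an unordered pair of lineages in deme d
      int r1 = (int)(unif_rand() * k[d]);
      int r2 = (int)(unif_rand() * (k[d] - 1));
      if (r2 >= r1) ++r2;
      int i1 = -1, i2 = -1, seen = 0;
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == d) {
          if (seen == r1) i1 = (int)i;
          if (seen == r2) i2 = (int)i;
          ++seen;
        }
      Branch b1, b2;
      b1.mask = act[i1].mask; b1.len = t - act[i1].btime;
      b2.mask = act[i2].mask; b2.len = t - act[i2].btime;
      branches.push_back(b1);
      branches.push_back(b2);
      if (recs) {
        CoalRec rc;
        rc.parent = nextnode;
        rc.c1 = act[i1].node;
        rc.c2 = act[i2].node;
        rc.time = t;
        recs->push_back(rc);
      }
      act[i1].mask |= act[i2].mask;
      act[i1].btime = t;
      act[i1].node = nextnode++;
      act.erase(act.begin() + i2);
      --k[d];
    } else {
      // migration out of deme d: pick lineage, pick destination
      int r = (int)(unif_rand() * k[d]);
      int idx = -1, seen = 0;
      for (size_t i = 0; i < act.size(); ++i)
        if (act[i].deme == d) {
          if (seen == r) { idx = (int)i; break; }
          ++seen;
        }
      double v = unif_rand() * A.migrow[epoch][d];
      int j = 0;
      for (j = 0; j < A.nd; ++j) {
        v -= A.mig[epoch][d * A.nd + j];
        if (v < 0) break;
      }
      if (j == A.nd) j = A.nd - 1;
      --k[d];
      act[idx].deme = j;
      ++k[j];
    }
  }
}

int pick_branch(const std::vector<Branch> &br, double tot) {
  double x = unif_rand() * tot;
  for (size_t i = 0; i < br.size(); ++i) {
    x -= br[i].len;
    if (x < 0) return (int)i;
  }
  return (int)br.size() - 1;
}

}  // namespace

// Unlinked-SNP sampler.  Site patterns must follow the low-mutation-rate
// infinite-sites distribution P(pattern i) = E[L_i] / E[L_total]; picking
// one branch per genealogy would instead give E[L_i / L_total] (trees are
// not size-biased by their length), which visibly distorts the SFS at
// small n.  We therefore run a Poisson mutation process over independent
// genealogies with a small per-tree intensity (calibrated from a warm-up
// batch), so each emitted site has the exact marginal distribution and
// almost every site comes from its own genealogy.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_sim_unlinked(NumericVector event_times, IntegerMatrix events,
                               NumericVector sizes, NumericVector mig,
                               IntegerVector samples, int n_snps,
                               double per_tree = 0.2) {
  EngineArgs A = unpack(event_times, events, sizes, mig, samples);
  IntegerMatrix out(n_snps, A.ntip);
  std::vector<Branch> br;
  // warm-up: estimate the mean total tree length
  const int warm = 50;
  double meanL = 0.0;
  for (int w = 0; w < warm; ++w) {
    sim_tree(A, br, nullptr);
    for (size_t i = 0; i < br.size(); ++i) meanL += br[i].len;
  }
  meanL /= warm;
  double theta = per_tree / meanL;
  int s = 0;
  while (s < n_snps) {
    sim_tree(A, br, nullptr);
    double tot = 0.0;
    for (size_t i = 0; i < br.size(); ++i) tot += br[i].len;
    int nmut = (int)R::rpois(theta * tot);
    for (int j = 0; j < nmut && s < n_snps; ++j, ++s) {
      uint64_t m = br[pick_branch(br, tot)].mask;
      for (int tp = 0; tp < A.ntip; ++tp)
        out(s, tp) = (int)((m >> tp) & 1);
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_sim_locus(NumericVector event_times, IntegerMatrix events,
                   NumericVector sizes, NumericVector mig,
                   IntegerVector samples, int length_bp, double mu) {
  EngineArgs A = unpack(event_times, events, sizes, mig, samples);
  std::vector<Branch> br;
  sim_tree(A, br, nullptr);
  double tot = 0.0;
  for (size_t i = 0; i < br.size(); ++i) tot += br[i].len;
  int nmut = (int)R::rpois(tot * mu * (double)length_bp);
  if (nmut > length_bp)
    stop("locus saturated: %d mutations on %d sites (infinite-sites violated)",
         nmut, length_bp);
  // distinct positions, 1-based, via rejection (nmut << length in practice)
  std::vector<int> pos;
  std::vector<bool> used(length_bp + 1, false);
  while ((int)pos.size() < nmut) {
    int p = 1 + (int)(unif_rand() * length_bp);
    if (p > length_bp) p = length_bp;
    if (!used[p]) { used[p] = true; pos.push_back(p); }
  }
  std::sort(pos.begin(), pos.end());
  IntegerMatrix geno(nmut, A.ntip);
  for (int s = 0; s < nmut; ++s) {
    uint64_t m = br[pick_branch(br, tot)].mask;
    for (int tp = 0; tp < A.ntip; ++tp)
      geno(s, tp) = (int)((m >> tp) & 1);
  }
  return List::create(_["geno"] = geno, _["positions"] = wrap(pos),
                      _["tree_length"] = tot);
}

//' @noRd
// [[Rcpp::export]]
List cpp_sim_genealogy(NumericVector event_times, IntegerMatrix events,
                       NumericVector sizes, NumericVector mig,
                       IntegerVector samples) {
  EngineArgs A = unpack(event_times, events, sizes, mig, samples);
  std::vector<Branch> br;
  std::vector<CoalRec> recs;
  sim_tree(A, br, &recs);
  int m = (int)recs.size();
  IntegerVector parent(2 * m), child(2 * m);
  NumericVector ptime(2 * m), tip_deme(A.ntip);
  NumericVector ntime(A.ntip + m, 0.0);  // creation time per node id
  for (int i = 0; i < m; ++i) ntime[recs[i].parent] = recs[i].time;
  for (int i = 0; i < m; ++i) {
    parent[2 * i] = recs[i].parent;
    child[2 * i] = recs[i].c1;
    parent[2 * i + 1] = recs[i].parent;
    child[2 * i + 1] = recs[i].c2;
    ptime[2 * i] = recs[i].time;
    ptime[2 * i + 1] = recs[i].time;
  }
  int tp = 0;
  for (int d = 0; d < A.nd; ++d)
    for (int i = 0; i < A.samples[d]; ++i) tip_deme[tp++] = d;
  return List::create(_["parent"] = parent, _["child"] = child,
                      _["parent_time"] = ptime, _["node_time"] = ntime,
                      _["n_tip"] = A.ntip, _["tip_deme"] = tip_deme);
}
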