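#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Structured-coalescent site-pattern sampler for the four-population
// phylogeny (((P1,P2),P3),O) with an optional admixture pulse P3 -> P2.
//
// Population codes:
//   0 = P1, 1 = P2, 2 = P3, 3 = O,
//   4 = ancestor of (P1,P2), 5 = ancestor of (P1,P2,P3), 6 = root,
//   7 = P2 lineages carrying donor ancestry at this locus (tract mode);
//       they coalesce among themselves at the P2 rate and jump to P3 at
//       the pulse time, so a donor-tract lineage can never coalesce with a
//       non-introgressed P2 lineage more recently than the pulse.
//
// Times are in generations before present; ne are diploid effective sizes
// (pairwise coalescence rate 1/(2*Ne) per generation). All randomness goes
// through R's RNG so set.seed() on the R side gives full reproducibility.

namespace {

struct Node {
  double time;
  uint64_t leaves;
  double branch; // length to parent; -1 until the node is joined
};

struct Sim {
  std::vector<int> active;        // node ids of live lineages
  std::vector<int> pop;           // population of each live lineage
  std::vector<Node> nodes;
  double ne[8];

  void merge_random_pair(int which_pop, double t) {
    std::vector<int> idx;
    for (size_t i = 0; i < active.size(); ++i)
      if (pop[i] == which_pop) idx.push_back((int)i);
    int k = (int)idx.size();
    int a = (int)(R::unif_rand() * k);
    if (a >= k) a = k - 1;
    int b = (int)(R::unif_rand() * (k - 1));
    if (b >= k - 1) b = k - 2;
    if (b >= a) ++b;
    int ia = idx[a], ib = idx[b];
    int na = active[ia], nb = active[ib];
    Node parent;
    parent.time = t;
    parent.leaves = nodes[na].leaves | nodes[nb].leaves;
    parent.branch = -1.0;
    nodes[na].branch = t - nodes[na].time;
    nodes[nb].branch = t - nodes[nb].time;
    nodes.push_back(parent);
    int pid = (int)nodes.size() - 1;
    active[ia] = pid; // pop unchanged
    active.erase(active.begin() + ib);
    pop.erase(pop.begin() + ib);
  }

  // run the coalescent from time `cur` to `end` (possibly infinite)
  double coalesce(double cur, double end) {
    for (;;) {
      double rate = 0.0, by_pop[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      int count[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (size_t i = 0; i < active.size(); ++i) count[pop[i]]++;
      for (int p = 0; p < 8; ++p) {
        if (count[p] >= 2) {
          by_pop[p] = count[p] * (count[p] - 1) / 2.0 / (2.0 * ne[p]);
          rate += by_pop[p];
        }
      }
      if (rate <= 0.0) return end;
      double wait = R::exp_rand() / rate;
      if (!R_FINITE(end) || cur + wait < end) {
        cur += wait;
        double u = R::unif_rand() * rate;
        int p = 0;
        for (; p < 7; ++p) {
          if (u < by_pop[p]) break;
          u -= by_pop[p];
        }
        merge_random_pair(p, cur);
        if (active.size() == 1) return cur;
      } else {
        return end;
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List sim_patterns_cpp(IntegerVector leaf_pop, NumericVector ne,
                      double t12, double t123, double t_out,
                      double t_pulse, double pulse_f,
                      int n_trees, double mu_block) {
  const int L = leaf_pop.size();
  if (L < 2 || L > 64) stop("between 2 and 64 haploid lineages supported");
  if (ne.size() != 8) stop("ne must have length 8");
  if (!(t12 < t123 && t123 < t_out)) stop("need t12 < t123 < t_out");
  bool tract_mode = false;
  for (int i = 0; i < L; ++i) {
    if (leaf_pop[i] == 7) tract_mode = true;
    if (leaf_pop[i] != 0 && leaf_pop[i] != 1 && leaf_pop[i] != 2 &&
        leaf_pop[i] != 3 && leaf_pop[i] != 7)
      stop("leaf populations must be 0,1,2,3 or 7");
  }
  bool has_pulse = (pulse_f > 0.0) || tract_mode;
  if (has_pulse && !(t_pulse > 0.0 && t_pulse < t12))
    stop("pulse time must lie in (0, t12)");

  std::vector<uint64_t> site_mask;
  std::vector<int> site_tree;

  for (int tr = 0; tr < n_trees; ++tr) {
    Sim s;
    for (int p = 0; p < 8; ++p) s.ne[p] = ne[p];
    s.nodes.reserve(2 * L);
    for (int i = 0; i < L; ++i) {
      Node nd;
      nd.time = 0.0;
      nd.leaves = (uint64_t)1 << i;
      nd.branch = -1.0;
      s.nodes.push_back(nd);
      s.active.push_back(i);
      s.pop.push_back(leaf_pop[i]);
    }
    double cur = 0.0;
    if (has_pulse) {
      cur = s.coalesce(cur, t_pulse);
      for (size_t i = 0; i < s.pop.size(); ++i) {
        if (s.pop[i] == 7) {
          s.pop[i] = 2;
        } else if (s.pop[i] == 1 && pulse_f > 0.0 &&
                   R::unif_rand() < pulse_f) {
          s.pop[i] = 2;
        }
      }
    }
    cur = s.coalesce(cur, t12);
    for (size_t i = 0; i < s.pop.size(); ++i)
      if (s.pop[i] == 0 || s.pop[i] == 1 || s.pop[i] == 7) s.pop[i] = 4;
    cur = s.coalesce(cur, t123);
    for (size_t i = 0; i < s.pop.size(); ++i)
      if (s.pop[i] == 4 || s.pop[i] == 2) s.pop[i] = 5;
    cur = s.coalesce(cur, t_out);
    for (size_t i = 0; i < s.pop.size(); ++i) s.pop[i] = 6;
    s.coalesce(cur, R_PosInf);

    // mutation placement: pick branches with probability proportional
    // to their length (infinite-sites; one biallelic SNP per mutation)
    double total = 0.0;
    for (size_t i = 0; i + 1 < s.nodes.size(); ++i)
      if (s.nodes[i].branch > 0) total += s.nodes[i].branch;
    int nmut = (mu_block <= 0.0) ? 1 : (int)R::rpois(mu_block * total);
    for (int m = 0; m < nmut; ++m) {
      double u = R::unif_rand() * total, acc = 0.0;
      uint64_t mask = 0;
      for (size_t i = 0; i + 1 < s.nodes.size(); ++i) {
        if (s.nodes[i].branch > 0) {
          acc += s.nodes[i].branch;
          if (u <= acc) {
            mask = s.nodes[i].leaves;
            break;
          }
        }
      }
      if (mask == 0) mask = s.nodes[0].leaves; // numerical edge case
      site_mask.push_back(mask);
      site_tree.push_back(tr + 1);
    }
  }

  const int S = (int)site_mask.size();
  IntegerMatrix pat(S, L);
  IntegerVector tree(S);
  for (int r = 0; r < S; ++r) {
    tree[r] = site_tree[r];
    for (int c = 0; c < L; ++c)
      pat(r, c) = (site_mask[r] >> c) & 1 ? 1 : 0;
  }
  return List::create(_["patterns"] = pat, _["tree"] = tree);
}
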