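// Multi-population coalescent SNP simulator.
//
// Simulates, locus by locus, an independent genealogy of all sampled
// lineages under a demography of constant-size populations connected by
// split and admixture events (times in generations, looking backward), then
// places exactly one mutation on a branch chosen with probability
// proportional to branch length. Because every branch subtends between 1
// and n-1 samples, each locus is polymorphic in the pooled sample by
// construction (SNP-ascertained data; no per-site mutation rate enters).
//
// Events (rows of `events`, processed in increasing time order, ties in row
// order):
//   type 0 (split, backward merge): all lineages in pop a move to pop b.
//   type 1 (admixture pulse):      each lineage in pop a moves to pop b
//                                  with probability `rate`, else to pop c
//                                  (c may equal a, i.e. stay).
//
// Uses R's RNG so results are reproducible through set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// workspace reused across loci to avoid per-locus allocation
struct Sim {
  std::vector<int> node, pop;        // active lineages
  std::vector<double> start;         // segment start time per active lineage
  std::vector<int> k;                // active lineage count per population
  std::vector<int> edge_child;       // edge list (child node below the edge)
  std::vector<double> edge_len;
  std::vector<int> left, right;      // children per internal node
  std::vector<int> stack;
  double tmrca, total_length;
  int n_leaves;
};

void simulate_tree(Sim& S, const NumericVector& pop_size,
                   const NumericMatrix& events, const IntegerVector& n_hap) {
  const int n_pops = pop_size.size();
  S.node.clear(); S.pop.clear(); S.start.clear();
  S.edge_child.clear(); S.edge_len.clear();
  S.k.assign(n_pops, 0);
  int next_node = 0;
  for (int p = 0; p < n_pops; ++p) {
    for (int i = 0; i < n_hap[p]; ++i) {
      S.node.push_back(next_node++);
      S.pop.push_back(p);
      S.start.push_back(0.0);
    }
    S.k[p] = n_hap[p];
  }
  S.n_leaves = next_node;
  S.left.assign(2 * S.n_leaves - 1, -1);
  S.right.assign(2 * S.n_leaves - 1, -1);
  S.total_length = 0.0;

  double t = 0.0;
  int next_ev = 0;
  const int n_ev = events.nrow();

  while ((int)S.node.size() > 1) {
    double total_rate = 0.0;
    for (int p = 0; p < n_pops; ++p)
      if (S.k[p] > 1)
        total_rate += S.k[p] * (S.k[p] - 1.0) / (4.0 * pop_size[p]);

    double t_ev = (next_ev < n_ev) ? events(next_ev, 0) : R_PosInf;
    double wait = (total_rate > 0.0) ? exp_rand() / total_rate : R_PosInf;

    if (t + wait >= t_ev) {
      t = t_ev;
      int type = (int)events(next_ev, 1);
      int a = (int)events(next_ev, 2);
      int b = (int)events(next_ev, 3);
      if (type == 0) {
        for (size_t i = 0; i < S.pop.size(); ++i)
          if (S.pop[i] == a) S.pop[i] = b;
        S.k[b] += S.k[a];
        S.k[a] = 0;
      } else {
        int c = (int)events(next_ev, 4);
        double rate = events(next_ev, 5);
        for (size_t i = 0; i < S.pop.size(); ++i) {
          if (S.pop[i] == a) {
            int dest = (unif_rand() < rate) ? b : c;
            if (dest != a) { --S.k[a]; ++S.k[dest]; S.pop[i] = dest; }
          }
        }
      }
      ++next_ev;
      continue;
    }

    t += wait;
    // population in which the coalescence happens, proportional to rate
    double u = unif_rand() * total_rate, acc = 0.0;
    int cp = -1;
    for (int p = 0; p < n_pops; ++p) {
      if (S.k[p] > 1) {
        acc += S.k[p] * (S.k[p] - 1.0) / (4.0 * pop_size[p]);
        if (u <= acc) { cp = p; break; }
      }
    }
    if (cp < 0) continue;  // numerical guard
    // unordered pair uniform within that population
    int i1 = (int)(unif_rand() * S.k[cp]);
    int i2 = (int)(unif_rand() * (S.k[cp] - 1));
    if (i2 >= i1) ++i2;
    int seen = 0, ia = -1, ib = -1;
    for (size_t idx = 0; idx < S.pop.size(); ++idx) {
      if (S.pop[idx] == cp) {
        if (seen == i1) ia = (int)idx;
        if (seen == i2) ib = (int)idx;
        ++seen;
        if (ia >= 0 && ib >= 0 && seen > std::max(i1, i2)) break;
      }
    }
    S.edge_child.push_back(S.node[ia]);
    S.edge_len.push_back(t - S.start[ia]);
    S.edge_child.push_back(S.node[ib]);
    S.edge_len.push_back(t - S.start[ib]);
    S.total_length += (t - S.start[ia]) + (t - S.start[ib]);
    S.left[next_node] = S.node[ia];
    S.right[next_node] = S.node[ib];
    S.node[ia] = next_node++;
    S.start[ia] = t;
    // swap-remove ib (lineage order carries no meaning)
    S.node[ib] = S.node.back(); S.node.pop_back();
    S.pop[ib] = S.pop.back(); S.pop.pop_back();
    S.start[ib] = S.start.back(); S.start.pop_back();
    --S.k[cp];
  }
  S.tmrca = t;
}

// place one mutation with probability proportional to branch length and
// mark the derived leaves
void drop_mutation(Sim& S, std::vector<char>& derived) {
  double u = unif_rand() * S.total_length, acc = 0.0;
  int chosen = S.edge_child.back();
  for (size_t e = 0; e < S.edge_len.size(); ++e) {
    acc += S.edge_len[e];
    if (u <= acc) { chosen = S.edge_child[e]; break; }
  }
  derived.assign(S.n_leaves, 0);
  S.stack.clear();
  S.stack.push_back(chosen);
  while (!S.stack.empty()) {
    int nd = S.stack.back(); S.stack.pop_back();
    if (nd < S.n_leaves) { derived[nd] = 1; continue; }
    S.stack.push_back(S.left[nd]);
    S.stack.push_back(S.right[nd]);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_loci(NumericVector pop_size, NumericMatrix events,
                       IntegerVector n_hap, int n_loci,
                       bool genotypes, bool tmrca) {
  const int n_pops = pop_size.size();
  int n_leaves = 0;
  for (int p = 0; p < n_pops; ++p) n_leaves += n_hap[p];
  if (n_leaves < 2) stop("need at least two sampled lineages");

  IntegerMatrix counts(n_loci, n_pops);
  IntegerMatrix hap;
  if (genotypes) hap = IntegerMatrix(n_loci, n_leaves);
  NumericVector tm, tl;
  if (tmrca) { tm = NumericVector(n_loci); tl = NumericVector(n_loci); }

  Sim S;
  std::vector<char> derived;
  for (int l = 0; l < n_loci; ++l) {
    simulate_tree(S, pop_size, events, n_hap);
    drop_mutation(S, derived);
    int leaf = 0;
    for (int p = 0; p < n_pops; ++p) {
      int c = 0;
      for (int i = 0; i < n_hap[p]; ++i, ++leaf) {
        if (derived[leaf]) ++c;
        if (genotypes) hap(l, leaf) = derived[leaf];
      }
      counts(l, p) = c;
    }
    if (tmrca) { tm[l] = S.tmrca; tl[l] = S.total_length; }
  }

  List out = List::create(Named("counts") = counts);
  if (genotypes) out["haplotypes"] = hap;
  if (tmrca) { out["tmrca"] = tm; out["tree_length"] = tl; }
  return out;
}
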