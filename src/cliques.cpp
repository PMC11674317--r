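#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Directed flag complex enumeration.
//
// A k-simplex is an ordered tuple (v0, ..., vk) of distinct vertices with
// an edge vi -> vj for every i < j.  Enumeration proceeds per starting
// vertex: the candidate set for extending a tuple is the intersection of
// the out-neighbourhoods of all its members, maintained incrementally as
// a sorted vector.  With a kernel filter, a tuple is counted iff at least
// one member is a kernel vertex (the filter cannot prune branches, since
// a kernel vertex may join later).

struct FlagCounter {
  const std::vector<std::vector<int>>& adj; // sorted out-neighbours, 0-based
  const std::vector<char>& kern;            // kernel mask (empty = no filter)
  bool filtered;
  int max_dim;
  bool keep;
  double keep_limit;
  std::vector<double> counts;               // per dimension
  std::vector<std::vector<int>> cliques;    // flattened tuples per dimension
  std::vector<int> cur;
  double kept_total = 0.0;

  FlagCounter(const std::vector<std::vector<int>>& a,
              const std::vector<char>& k, int md, bool kp, double kl)
      : adj(a), kern(k), filtered(!k.empty()), max_dim(md), keep(kp),
        keep_limit(kl), counts(md + 1, 0.0), cliques(md + 1) {}

  void record(int dim, bool has_kernel) {
    if (filtered && !has_kernel) return;
    counts[dim] += 1.0;
    if (keep) {
      kept_total += 1.0;
      if (kept_total > keep_limit)
        stop("clique list exceeds keep_limit (%g); raise the limit or "
             "disable keep_cliques", keep_limit);
      cliques[dim].insert(cliques[dim].end(), cur.begin(), cur.end());
    }
  }

  void extend(const std::vector<int>& cand, int dim, bool has_kernel) {
    if (dim >= max_dim) return;
    std::vector<int> next;
    for (int u : cand) {
      bool hk = has_kernel || (filtered && kern[u]);
      cur.push_back(u);
      record(dim + 1, hk);
      const std::vector<int>& au = adj[u];
      next.clear();
      std::set_intersection(cand.begin(), cand.end(), au.begin(), au.end(),
                            std::back_inserter(next));
      if (!next.empty()) extend(next, dim + 1, hk);
      cur.pop_back();
    }
  }

  void run() {
    int n = adj.size();
    for (int v = 0; v < n; ++v) {
      bool hk = filtered && kern[v];
      cur.assign(1, v);
      record(0, hk);
      if (!adj[v].empty()) extend(adj[v], 0, hk);
    }
    cur.clear();
  }
};

// [[Rcpp::export]]
List flag_count_cpp(int n, List adj_list, IntegerVector kernel_mask,
                    int max_dim, bool keep_cliques, double keep_limit) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj_list[i];
    adj[i].assign(nb.begin(), nb.end());
    for (int& x : adj[i]) x -= 1; // to 0-based
    std::sort(adj[i].begin(), adj[i].end());
  }
  std::vector<char> kern;
  if (kernel_mask.size() > 0) {
    if (kernel_mask.size() != n) stop("kernel mask length must equal n");
    kern.assign(kernel_mask.begin(), kernel_mask.end());
  }
  FlagCounter fc(adj, kern, max_dim, keep_cliques, keep_limit);
  fc.run();

  NumericVector counts(max_dim + 1);
  for (int d = 0; d <= max_dim; ++d) counts[d] = fc.counts[d];
  List cl(max_dim + 1);
  if (keep_cliques) {
    for (int d = 0; d <= max_dim; ++d) {
      int k = d + 1;
      int nc = fc.cliques[d].size() / k;
      IntegerMatrix m(nc, k);
      for (int i = 0; i < nc; ++i)
        for (int j = 0; j < k; ++j)
          m(i, j) = fc.cliques[d][i * k + j] + 1; // back to 1-based
      cl[d] = m;
    }
  }
  return List::create(_["counts"] = counts, _["cliques"] = cl);
}
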