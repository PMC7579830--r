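#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive DFS enumeration of all paths of length 1..max_len starting
// at every node of an undirected graph given as a 1-based adjacency
// list.  With simple_only, no node repeats within a path.  Emission
// order is deterministic: targets in index order, then DFS pre-order
// over the (sorted) adjacency lists, so downstream grouping is
// reproducible given the input ordering.
//
// The type id encodes the node-class sequence: classes (0 = M, 1 = D)
// at positions 0..L form a binary number with position p at weight 2^p,
// offset by the count of all shorter types.  This matches the order of
// enumerate_types().
// [[Rcpp::export]]
List cpp_extract_paths(List adj, IntegerVector node_class, int max_len,
                       bool simple_only) {
  const int N = adj.size();
  std::vector<std::vector<int> > nbr(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector v = adj[i];
    nbr[i].assign(v.begin(), v.end());
  }
  std::vector<int> offset(max_len + 2, 0);
  for (int l = 1; l <= max_len; ++l)
    offset[l + 1] = offset[l] + (1 << (l + 1));

  std::vector<int> out_nodes, out_len, out_type;
  out_nodes.reserve(1 << 16);
  std::vector<int> path;
  std::vector<size_t> it;
  std::vector<char> used(N + 1, 0);

  for (int s = 1; s <= N; ++s) {
    path.assign(1, s);
    it.assign(1, 0);
    used[s] = 1;
    while (!it.empty()) {
      int u = path.back();
      size_t &k = it.back();
      if ((int)path.size() - 1 < max_len && k < nbr[u - 1].size()) {
        int v = nbr[u - 1][k++];
        if (simple_only && used[v]) continue;
        path.push_back(v);
        if (simple_only) used[v] = 1;
        it.push_back(0);
        const int L = (int)path.size() - 1;
        int bits = 0;
        for (int p = 0; p <= L; ++p)
          bits |= node_class[path[p] - 1] << p;
        out_type.push_back(offset[L] + bits + 1);
        out_len.push_back(L);
        for (int p = 0; p <= L; ++p) out_nodes.push_back(path[p]);
        for (int p = L + 1; p <= max_len; ++p) out_nodes.push_back(0);
      } else {
        if (simple_only) used[u] = 0;
        path.pop_back();
        it.pop_back();
      }
    }
    used[s] = 0;
  }

  const R_xlen_t ni = out_len.size();
  IntegerMatrix paths(ni, max_len + 1);
  for (R_xlen_t r = 0; r < ni; ++r)
    for (int c = 0; c <= max_len; ++c)
      paths(r, c) = out_nodes[r * (max_len + 1) + c];
  return List::create(_["paths"] = paths,
                      _["len"] = IntegerVector(out_len.begin(), out_len.end()),
                      _["type"] = IntegerVector(out_type.begin(), out_type.end()));
}
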