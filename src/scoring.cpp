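#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Parsimony scoring kernels. Nucleotide states are bitmasks over A=1, C=2,
// G=4, T=8; IUPAC ambiguities are the corresponding unions and '?'/'-'/N are
// the full set 15 (missing data behaves as "any state").

// Minimum-change count for unordered characters on an arbitrary (possibly
// multifurcating) tree, by Hartigan's generalization of the Fitch
// set-intersection pass: at each internal node the preferred state set is the
// set of states occurring in the maximal number of children's preferred sets,
// and (arity - max count) changes are charged.
//
// edge: postorder edge matrix (parent, child), 1-based as in ape.
// states: nTip x nPattern bitmask matrix, rows in tip-id order.
// [[Rcpp::export]]
List fitch_count_cpp(IntegerMatrix edge, int nTip, IntegerMatrix states,
                     NumericVector weights) {
  const int nEdge = edge.nrow();
  const int nPat = states.ncol();
  int maxId = nTip;
  for (int e = 0; e < nEdge; ++e) {
    if (edge(e, 0) > maxId) maxId = edge(e, 0);
    if (edge(e, 1) > maxId) maxId = edge(e, 1);
  }
  IntegerVector perPattern(nPat);
  double total = 0.0;
  std::vector<int> cnt(4 * (maxId + 1));
  std::vector<int> arity(maxId + 1);
  std::vector<int> setv(maxId + 1);
  std::vector<char> done(maxId + 1);

  for (int p = 0; p < nPat; ++p) {
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(arity.begin(), arity.end(), 0);
    std::fill(done.begin(), done.end(), 0);
    int steps = 0;
    int root = edge(nEdge - 1, 0);
    for (int e = 0; e < nEdge; ++e) {
      int par = edge(e, 0), ch = edge(e, 1);
      int s;
      if (ch <= nTip) {
        s = states(ch - 1, p);
      } else {
        if (!done[ch]) {
          int K = 0;
          for (int b = 0; b < 4; ++b) if (cnt[4 * ch + b] > K) K = cnt[4 * ch + b];
          int v = 0;
          for (int b = 0; b < 4; ++b) if (cnt[4 * ch + b] == K) v |= (1 << b);
          steps += arity[ch] - K;
          setv[ch] = v;
          done[ch] = 1;
        }
        s = setv[ch];
      }
      for (int b = 0; b < 4; ++b) if (s & (1 << b)) cnt[4 * par + b]++;
      arity[par]++;
    }
    {
      int K = 0;
      for (int b = 0; b < 4; ++b) if (cnt[4 * root + b] > K) K = cnt[4 * root + b];
      steps += arity[root] - K;
    }
    perPattern[p] = steps;
    total += steps * weights[p];
  }
  return List::create(_["steps"] = perPattern, _["total"] = total);
}

// Accommodation test for three-taxon statements ij|k on a tree polarized at
// an outgroup leaf: a statement holds iff the smallest cluster (away from the
// outgroup) containing both i and j excludes k. Tips are 1-based ids; ogTip
// = 0 means "use the stored root" (tree already rooted).
// [[Rcpp::export]]
LogicalVector ts_violations_cpp(IntegerMatrix edge, int nTip, int ogTip,
                                IntegerVector si, IntegerVector sj,
                                IntegerVector sk) {
  const int nEdge = edge.nrow();
  int maxId = nTip;
  for (int e = 0; e < nEdge; ++e) {
    if (edge(e, 0) > maxId) maxId = edge(e, 0);
    if (edge(e, 1) > maxId) maxId = edge(e, 1);
  }
  // adjacency
  std::vector<std::vector<int>> adj(maxId + 1);
  for (int e = 0; e < nEdge; ++e) {
    adj[edge(e, 0)].push_back(edge(e, 1));
    adj[edge(e, 1)].push_back(edge(e, 0));
  }
  int start;
  if (ogTip >= 1) {
    start = ogTip; // root the traversal at the outgroup leaf
  } else {
    start = edge(nEdge - 1, 0); // stored root (postorder last parent)
    // fall back to a parentless node scan
    std::vector<char> isChild(maxId + 1, 0);
    for (int e = 0; e < nEdge; ++e) isChild[edge(e, 1)] = 1;
    for (int v = nTip + 1; v <= maxId; ++v)
      if (!isChild[v] && !adj[v].empty()) { start = v; break; }
  }
  std::vector<int> parent(maxId + 1, 0), depth(maxId + 1, 0), order;
  order.reserve(maxId + 1);
  std::vector<int> stack;
  stack.push_back(start);
  parent[start] = -1;
  std::vector<char> seen(maxId + 1, 0);
  seen[start] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (int w : adj[v]) {
      if (!seen[w]) {
        seen[w] = 1;
        parent[w] = v;
        depth[w] = depth[v] + 1;
        stack.push_back(w);
      }
    }
  }
  // leaf-set bitmasks per node, filled leaves-to-root
  const int words = (nTip + 63) / 64;
  std::vector<uint64_t> clus((maxId + 1) * (size_t)words, 0);
  for (int idx = (int)order.size() - 1; idx >= 0; --idx) {
    int v = order[idx];
    if (v <= nTip) clus[(size_t)v * words + (v - 1) / 64] |= (uint64_t)1 << ((v - 1) % 64);
    int pv = parent[v];
    if (pv >= 1)
      for (int w = 0; w < words; ++w)
        clus[(size_t)pv * words + w] |= clus[(size_t)v * words + w];
  }
  const int n = si.size();
  LogicalVector viol(n);
  for (int s = 0; s < n; ++s) {
    int a = si[s], b = sj[s], k = sk[s];
    // MRCA of a, b under the traversal rooting
    int x = a, y = b;
    while (depth[x] > depth[y]) x = parent[x];
    while (depth[y] > depth[x]) y = parent[y];
    while (x != y) { x = parent[x]; y = parent[y]; }
    viol[s] = (clus[(size_t)x * words + (k - 1) / 64] >> ((k - 1) % 64)) & 1;
  }
  return viol;
}
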