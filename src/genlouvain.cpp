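#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy multilayer-modularity maximization on a dense (generalized)
// modularity matrix B: randomized node-move sweeps until no single move
// raises the quality sum, then community aggregation, repeated until the
// partition is stable. Randomness (vertex scan order) comes from R's RNG,
// so set.seed() on the R side makes runs reproducible. Diagonal entries
// of B (null-model self terms) are constant under moves and ignored here;
// the R side evaluates Q on the full matrix.

static const double kTol = 1e-12;

// Fisher-Yates shuffle of 0..n-1 driven by R's RNG
static void shuffled_order(std::vector<int> &ord) {
  const int n = (int)ord.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// one level of local moving on the aggregated matrix M (n x n, dense,
// symmetric); comm is modified in place; returns true if any move happened
static bool local_move(const std::vector<double> &M, int n,
                       std::vector<int> &comm) {
  std::vector<int> ord(n);
  std::vector<double> s(n);
  std::vector<int> csize(n, 1);
  bool any = false, moved = true;
  while (moved) {
    moved = false;
    shuffled_order(ord);
    for (int k = 0; k < n; ++k) {
      const int u = ord[k];
      std::fill(s.begin(), s.end(), 0.0);
      const double *col = &M[(size_t)u * n];
      for (int v = 0; v < n; ++v)
        if (v != u) s[comm[v]] += col[v];
      const int cu = comm[u];
      // candidate gains relative to leaving u isolated; staying put has
      // value s[cu], an empty community has value 0
      double best = (csize[cu] > 1) ? 0.0 : s[cu];
      int bestc = (csize[cu] > 1) ? -1 : cu;
      for (int c = 0; c < n; ++c) {
        if (csize[c] == 0 && c != cu) continue;
        if (s[c] > best + kTol) { best = s[c]; bestc = c; }
      }
      if (bestc == -1) {  // move to a fresh empty community
        for (int c = 0; c < n; ++c)
          if (csize[c] == 0) { bestc = c; break; }
      }
      if (bestc != cu && best > s[cu] + kTol) {
        csize[cu]--; csize[bestc]++;
        comm[u] = bestc;
        moved = true; any = true;
      }
    }
  }
  return any;
}

// [[Rcpp::export]]
IntegerVector cpp_genlouvain(NumericMatrix B) {
  const int V = B.nrow();
  if (B.ncol() != V) stop("B must be square");
  std::vector<double> M(B.begin(), B.end());
  int n = V;
  std::vector<int> assign(V);           // original vertex -> aggregated node
  for (int i = 0; i < V; ++i) assign[i] = i;
  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;

  while (true) {
    bool any = local_move(M, n, comm);
    // relabel communities contiguously
    std::vector<int> remap(n, -1);
    int K = 0;
    for (int i = 0; i < n; ++i)
      if (remap[comm[i]] == -1) remap[comm[i]] = K++;
    for (int i = 0; i < V; ++i) assign[i] = remap[comm[assign[i]]];
    if (!any || K == n) break;
    // aggregate M into K x K
    std::vector<double> M2((size_t)K * K, 0.0);
    for (int i = 0; i < n; ++i) {
      const int ci = remap[comm[i]];
      for (int j = 0; j < n; ++j)
        M2[(size_t)ci * K + remap[comm[j]]] += M[(size_t)i * n + j];
    }
    M.swap(M2);
    n = K;
    comm.resize(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
  }

  IntegerVector out(V);
  for (int i = 0; i < V; ++i) out[i] = assign[i] + 1;
  return out;
}
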