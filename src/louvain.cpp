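#include <Rcpp.h>
using namespace Rcpp;

// Greedy Louvain (node moving + aggregation) on a precomputed symmetric
// modularity matrix B, maximising sum_{ij in same module} B_ij. This is the
// generalised form used for signed asymmetric modularity, where B already
// folds in the positive/negative null models and their 1/v weights.
// Node visit order is randomised through R's RNG so set.seed() in R gives
// bit-identical partitions.

// [[Rcpp::export]]
List louvain_modmat(NumericMatrix B, double tol) {
  const int n = B.nrow();
  std::vector<int> node2final(n);
  for (int i = 0; i < n; ++i) node2final[i] = i;

  std::vector<double> W(B.begin(), B.end());
  int nw = n;

  for (;;) {
    std::vector<int> comm(nw);
    for (int i = 0; i < nw; ++i) comm[i] = i;
    bool moved_any = false, sweep_moved = true;
    std::vector<double> csum(nw);
    std::vector<int> order(nw);

    while (sweep_moved) {
      sweep_moved = false;
      for (int i = 0; i < nw; ++i) order[i] = i;
      for (int i = nw - 1; i > 0; --i) {           // Fisher-Yates via R RNG
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      for (int oi = 0; oi < nw; ++oi) {
        const int i = order[oi];
        std::fill(csum.begin(), csum.end(), 0.0);
        for (int j = 0; j < nw; ++j) csum[comm[j]] += W[i + (size_t)nw * j];
        const int ci = comm[i];
        // self-loop B_ii travels with i: it cancels in every move gain
        const double cur = csum[ci] - W[i + (size_t)nw * i];
        int best = ci;
        double bestgain = tol;
        for (int c = 0; c < nw; ++c) {
          if (c == ci) continue;
          const double gain = csum[c] - cur;
          if (gain > bestgain) { bestgain = gain; best = c; }
        }
        if (best != ci) { comm[i] = best; sweep_moved = true; moved_any = true; }
      }
    }

    std::vector<int> remap(nw, -1);
    int M = 0;
    for (int i = 0; i < nw; ++i) if (remap[comm[i]] < 0) remap[comm[i]] = M++;
    for (int i = 0; i < nw; ++i) comm[i] = remap[comm[i]];
    for (int v = 0; v < n; ++v) node2final[v] = comm[node2final[v]];
    if (!moved_any || M == nw) break;

    std::vector<double> W2((size_t)M * M, 0.0);
    for (int j = 0; j < nw; ++j)
      for (int i = 0; i < nw; ++i)
        W2[comm[i] + (size_t)M * comm[j]] += W[i + (size_t)nw * j];
    W.swap(W2);
    nw = M;
  }

  // relabel by first appearance over original node order
  int M = 0;
  std::vector<int> remap(n, -1);
  for (int i = 0; i < n; ++i) if (remap[node2final[i]] < 0) remap[node2final[i]] = M++;

  double Q = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (node2final[i] == node2final[j]) Q += B(i, j);

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = remap[node2final[i]] + 1;
  return List::create(_["membership"] = out, _["n_modules"] = M, _["q"] = Q);
}
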