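// Exhaustive attractor/basin enumeration over the 2^n_free internal state
// space for one fixed control state.
//
// Strategy: materialize the full synchronous-update transition map once
// (next[s] for every encoded state s), then resolve attractors and basins by
// functional-graph traversal with a colouring array. Each state is visited a
// constant number of times, so the whole enumeration is O(2^n_free * E).
//
// The threshold rule s_i' = [2*r_i > n_i - 2*m_i] is evaluated in integer
// arithmetic; contributions of fixed nodes (controls, clamped nodes) are
// folded into base_r before the scan.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List engine_enumerate(int n_free, List reg_idx, List reg_sign,
                      IntegerVector base_r, IntegerVector rhs) {
  if (n_free < 1 || n_free > 30)
    stop("n_free out of supported range [1, 30]");
  const long long S = 1LL << n_free;
  const int K = base_r.size();
  if (K != n_free || reg_idx.size() != K || reg_sign.size() != K ||
      rhs.size() != K)
    stop("inconsistent engine inputs");

  // flatten per-node regulator lists
  std::vector<int> off(K + 1, 0), idx, sgn, br(K), th(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector ii = reg_idx[i], ss = reg_sign[i];
    if (ii.size() != ss.size()) stop("regulator index/sign length mismatch");
    off[i + 1] = off[i] + ii.size();
    for (int j = 0; j < ii.size(); ++j) {
      if (ii[j] < 0 || ii[j] >= n_free) stop("regulator index out of range");
      idx.push_back(ii[j]);
      sgn.push_back(ss[j]);
    }
    br[i] = base_r[i];
    th[i] = rhs[i];
  }

  std::vector<int> nxt(S);
  for (long long s = 0; s < S; ++s) {
    int out = 0;
    for (int i = 0; i < K; ++i) {
      int r = br[i];
      for (int e = off[i]; e < off[i + 1]; ++e)
        r += (int)((s >> idx[e]) & 1LL) * sgn[e];
      if (2 * r > th[i]) out |= (1 << i);
    }
    nxt[s] = out;
    if ((s & 0xFFFFF) == 0) checkUserInterrupt();
  }

  std::vector<int> label(S, -1);
  std::vector<long long> path, basin;
  std::vector< std::vector<int> > cycles;
  for (long long s0 = 0; s0 < S; ++s0) {
    if (label[s0] >= 0) continue;
    path.clear();
    long long cur = s0;
    while (label[cur] == -1) {
      label[cur] = -2;             // on current path
      path.push_back(cur);
      cur = nxt[cur];
    }
    int id;
    if (label[cur] == -2) {        // new cycle discovered within this path
      id = (int)cycles.size();
      size_t pos = path.size() - 1;
      while (path[pos] != cur) --pos;
      cycles.push_back(std::vector<int>(path.begin() + pos, path.end()));
      basin.push_back(0);
    } else {
      id = label[cur];
    }
    for (size_t k = 0; k < path.size(); ++k) label[path[k]] = id;
    basin[id] += (long long)path.size();
    if ((s0 & 0xFFFFF) == 0) checkUserInterrupt();
  }

  const int A = (int)cycles.size();
  List out_cycles(A);
  NumericVector bs(A);
  for (int a = 0; a < A; ++a) {
    out_cycles[a] = IntegerVector(cycles[a].begin(), cycles[a].end());
    bs[a] = (double)basin[a];
  }
  return List::create(_["cycles"] = out_cycles, _["basin_sizes"] = bs);
}
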