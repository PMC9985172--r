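#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy best-chain-first extraction of collinear blocks for one scaffold
// pair.  Anchors must be pre-sorted by (rank_a, rank_b).  A chain visits
// anchors with strictly increasing rank_a; consecutive anchors satisfy
// 1 <= delta(rank_a) <= m+1 and 1 <= dir*delta(rank_b) <= m+1 where
// dir = +1 (same orientation) or -1 (inverted).  The maximum-anchor-count
// chain is extracted repeatedly (ties: smaller total gap, then the
// lexicographically smallest anchor-index sequence; '+' preferred over '-'
// on exact ties), its anchors removed, until the best chain falls below s.

static std::vector<int> chain_of(const std::vector<int>& parent, int end) {
  std::vector<int> out;
  for (int i = end; i >= 0; i = parent[i]) out.push_back(i);
  std::reverse(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
List chain_dp(IntegerVector rank_a, IntegerVector rank_b, int s, int m) {
  int n = rank_a.size();
  std::vector<bool> active(n, true);
  IntegerVector block(n, 0);
  std::vector<std::string> orient;
  int next_block = 1;

  for (;;) {
    int best_len = 0;
    long best_gap = 0;
    std::vector<int> best_chain;
    int best_dir = 0;

    for (int diri = 0; diri < 2; ++diri) {
      int dir = (diri == 0) ? 1 : -1;
      std::vector<int> len(n, 0), parent(n, -1);
      std::vector<long> gap(n, 0);
      for (int i = 0; i < n; ++i) {
        if (!active[i]) continue;
        len[i] = 1; gap[i] = 0; parent[i] = -1;
        for (int j = 0; j < i; ++j) {
          if (!active[j]) continue;
          int dA = rank_a[i] - rank_a[j];
          if (dA < 1 || dA > m + 1) continue;
          int dB = dir * (rank_b[i] - rank_b[j]);
          if (dB < 1 || dB > m + 1) continue;
          int clen = len[j] + 1;
          long cgap = gap[j] + (dA - 1) + (dB - 1);
          bool take = false;
          if (clen > len[i]) take = true;
          else if (clen == len[i]) {
            if (cgap < gap[i]) take = true;
            else if (cgap == gap[i] && parent[i] >= 0 && parent[i] != j) {
              std::vector<int> ca = chain_of(parent, j);
              std::vector<int> cb = chain_of(parent, parent[i]);
              take = std::lexicographical_compare(ca.begin(), ca.end(),
                                                  cb.begin(), cb.end());
            }
          }
          if (take) { len[i] = clen; gap[i] = cgap; parent[i] = j; }
        }
      }
      for (int i = 0; i < n; ++i) {
        if (!active[i] || len[i] == 0) continue;
        bool take = false;
        if (len[i] > best_len) take = true;
        else if (len[i] == best_len) {
          if (gap[i] < best_gap) take = true;
          else if (gap[i] == best_gap) {
            std::vector<int> ci = chain_of(parent, i);
            if (std::lexicographical_compare(ci.begin(), ci.end(),
                                             best_chain.begin(),
                                             best_chain.end()))
              take = true;
          }
        }
        if (take) {
          best_len = len[i]; best_gap = gap[i];
          best_chain = chain_of(parent, i); best_dir = dir;
        }
      }
    }

    if (best_len < s) break;
    for (size_t k = 0; k < best_chain.size(); ++k) {
      block[best_chain[k]] = next_block;
      active[best_chain[k]] = false;
    }
    orient.push_back(best_dir == 1 ? "+" : "-");
    ++next_block;
  }

  return List::create(_["block"] = block, _["orientation"] = wrap(orient));
}
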