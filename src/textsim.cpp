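// Fuzzy string-similarity ratios used by key-phrase de-duplication.
//
// block_ratio mirrors the classic sequence-matcher similarity: recursively
// find the longest common contiguous block, recurse on the pieces to the
// left and right, and report 2*M / (|a| + |b|) where M is the total
// matched length.

#include <Rcpp.h>
#include <string>
#include <vector>

static int longest_block(const std::string& a, int alo, int ahi,
                         const std::string& b, int blo, int bhi,
                         int& best_i, int& best_j) {
  // DP over suffix-match lengths; O((ahi-alo)*(bhi-blo)) time
  int best = 0;
  best_i = alo;
  best_j = blo;
  std::vector<int> prev(bhi - blo + 1, 0), cur(bhi - blo + 1, 0);
  for (int i = alo; i < ahi; ++i) {
    for (int j = blo; j < bhi; ++j) {
      if (a[i] == b[j]) {
        cur[j - blo + 1] = prev[j - blo] + 1;
        if (cur[j - blo + 1] > best) {
          best = cur[j - blo + 1];
          best_i = i - best + 1;
          best_j = j - best + 1;
        }
      } else {
        cur[j - blo + 1] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

static int matched_total(const std::string& a, int alo, int ahi,
                         const std::string& b, int blo, int bhi) {
  if (alo >= ahi || blo >= bhi) return 0;
  int bi, bj;
  int len = longest_block(a, alo, ahi, b, blo, bhi, bi, bj);
  if (len == 0) return 0;
  return len + matched_total(a, alo, bi, b, blo, bj) +
         matched_total(a, bi + len, ahi, b, bj + len, bhi);
}

// [[Rcpp::export(name = ".block_ratio_cpp")]]
double block_ratio_cpp(std::string a, std::string b) {
  if (a.empty() && b.empty()) return 1.0;
  int m = matched_total(a, 0, (int)a.size(), b, 0, (int)b.size());
  return 2.0 * m / (double)(a.size() + b.size());
}
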