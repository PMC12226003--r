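#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exhaustive subset enumeration over phn-assigned genes on one contig.
// A subset is valid when its joint span (min start .. max end, inclusive)
// is <= W, it contains >= k distinct families, and every core family is
// present. Returns the maximal valid subsets as 1-based gene index vectors.
// Dynamic programming over bitmasks: min start / max end / family mask of a
// subset derive from the subset without its lowest bit. Memory is O(2^n);
// callers guard n <= 25.
// [[Rcpp::export]]
List bf_enumerate(IntegerVector starts, IntegerVector ends,
                  IntegerVector fam_idx, int W, int k,
                  IntegerVector core_idx) {
  const int n = starts.size();
  if (n == 0) return List::create();
  if (n > 25) stop("bf_enumerate: more than 25 genes");
  const std::uint64_t nmask = 1ULL << n;

  std::uint16_t coremask = 0;
  for (int i = 0; i < core_idx.size(); ++i) coremask |= (1u << core_idx[i]);

  std::vector<std::int32_t> minstart(nmask), maxend(nmask);
  std::vector<std::uint16_t> fmask(nmask, 0);
  std::vector<bool> valid(nmask, false);
  minstart[0] = INT32_MAX; maxend[0] = INT32_MIN;

  for (std::uint64_t m = 1; m < nmask; ++m) {
    int low = __builtin_ctzll(m);
    std::uint64_t rest = m & (m - 1);
    minstart[m] = std::min(minstart[rest], (std::int32_t)starts[low]);
    maxend[m] = std::max(maxend[rest], (std::int32_t)ends[low]);
    fmask[m] = fmask[rest] | (std::uint16_t)(1u << fam_idx[low]);
    long long span = (long long)maxend[m] - minstart[m] + 1;
    valid[m] = span <= W &&
               __builtin_popcount((unsigned)fmask[m]) >= k &&
               (fmask[m] & coremask) == coremask;
  }

  List out;
  for (std::uint64_t m = 1; m < nmask; ++m) {
    if (!valid[m]) continue;
    bool maximal = true;
    for (int j = 0; j < n && maximal; ++j) {
      std::uint64_t bit = 1ULL << j;
      if (!(m & bit) && valid[m | bit]) maximal = false;
    }
    if (!maximal) continue;
    IntegerVector idx;
    for (int j = 0; j < n; ++j) if (m & (1ULL << j)) idx.push_back(j + 1);
    out.push_back(idx);
  }
  return out;
}
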