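#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Popcount for one 64-bit word (portable; GCC/Clang map it to POPCNT).
static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int n = 0;
  while (x) { x &= x - 1; ++n; }
  return n;
#endif
}

// Pack the columns of a logical matrix into 64-bit words, one bit per row.
static std::vector<std::vector<uint64_t>> pack_columns(const LogicalMatrix& m) {
  int n = m.nrow(), p = m.ncol();
  int nw = (n + 63) / 64;
  std::vector<std::vector<uint64_t>> out(p, std::vector<uint64_t>(nw, 0));
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      if (m(i, j)) out[j][i >> 6] |= (uint64_t(1) << (i & 63));
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_count_filter_passes(LogicalMatrix pass_active,
                                      LogicalMatrix pass_inactive,
                                      IntegerMatrix combos) {
  // pass_* : molecules x pool-ranges membership matrices.
  // combos : filters x max_size, 1-based column indices, NA-padded.
  // Returns filters x 2 matrix of (tp, fp): molecules passing the conjunction.
  std::vector<std::vector<uint64_t>> bitsA = pack_columns(pass_active);
  std::vector<std::vector<uint64_t>> bitsI = pack_columns(pass_inactive);
  int nwA = (pass_active.nrow() + 63) / 64;
  int nwI = (pass_inactive.nrow() + 63) / 64;
  int nf = combos.nrow(), k = combos.ncol(), pool = pass_active.ncol();

  IntegerMatrix out(nf, 2);
  std::vector<uint64_t> accA(nwA), accI(nwI);
  for (int f = 0; f < nf; ++f) {
    bool first = true;
    for (int c = 0; c < k; ++c) {
      int j = combos(f, c);
      if (j == NA_INTEGER) continue;
      if (j < 1 || j > pool) stop("combo index out of range");
      const std::vector<uint64_t>& a = bitsA[j - 1];
      const std::vector<uint64_t>& b = bitsI[j - 1];
      if (first) {
        std::copy(a.begin(), a.end(), accA.begin());
        std::copy(b.begin(), b.end(), accI.begin());
        first = false;
      } else {
        for (int w = 0; w < nwA; ++w) accA[w] &= a[w];
        for (int w = 0; w < nwI; ++w) accI[w] &= b[w];
      }
    }
    int tp = 0, fp = 0;
    if (!first) {
      for (int w = 0; w < nwA; ++w) tp += popcount64(accA[w]);
      for (int w = 0; w < nwI; ++w) fp += popcount64(accI[w]);
    }
    out(f, 0) = tp;
    out(f, 1) = fp;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_combinations(int n, int k) {
  // All k-subsets of 1..n in lexicographic order, one row per subset.
  if (k < 0 || k > n) stop("need 0 <= k <= n");
  double total = 1;
  for (int i = 0; i < k; ++i) total = total * (n - i) / (i + 1);
  if (total > 2e8) stop("combination count too large to materialise");
  int nrow = (int) (total + 0.5);
  IntegerMatrix out(nrow, k);
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i + 1;
  int r = 0;
  while (true) {
    for (int i = 0; i < k; ++i) out(r, i) = idx[i];
    ++r;
    int i = k - 1;
    while (i >= 0 && idx[i] == n - k + i + 1) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return out;
}
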