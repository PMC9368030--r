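#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Relative bipartition information content of a replicate tree set after
// leaf removal. Each tree is given as a 0/1 matrix (rows = nontrivial
// bipartitions, columns = leaves in one fixed master order). Removing
// leaves restricts every bipartition to the kept leaf set; restricted
// bipartitions are canonicalized (flipped so the side not containing the
// first kept leaf is stored), deduplicated within each tree, tallied across
// trees, and the frequencies of all majority (> 1/2) splits are summed and
// divided by n0 - 3 with n0 = |original leaf set| held fixed, so removals
// cannot inflate the score trivially.

typedef std::vector<uint64_t> BV;

// splitmix64 finalizer; restricted bipartitions are tallied under a mixed
// 64-bit digest of their bit pattern (collisions are negligible at the
// replicate-set sizes involved and the score is a sum of frequencies, so a
// vanishingly rare collision perturbs it by at most one split)
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static std::vector<std::vector<BV>> pack_trees(const List &bipmats, int n0,
                                               int &nwords) {
  nwords = (n0 + 63) / 64;
  std::vector<std::vector<BV>> trees;
  trees.reserve(bipmats.size());
  for (int t = 0; t < bipmats.size(); ++t) {
    IntegerMatrix m = bipmats[t];
    if (m.ncol() != n0) stop("bipartition matrix has wrong leaf count");
    std::vector<BV> rows(m.nrow(), BV(nwords, 0));
    for (int r = 0; r < m.nrow(); ++r)
      for (int c = 0; c < n0; ++c)
        if (m(r, c)) rows[r][c >> 6] |= (uint64_t)1 << (c & 63);
    trees.push_back(std::move(rows));
  }
  return trees;
}

static double score_masked(const std::vector<std::vector<BV>> &trees,
                           const BV &mask, int m, int n0, int nwords) {
  if (m < 4) return NA_REAL;
  // first kept leaf (for canonical flipping)
  int fw = 0;
  uint64_t fb = 0;
  for (int w = 0; w < nwords; ++w) {
    if (mask[w]) {
      fw = w;
      fb = mask[w] & (~mask[w] + 1);  // lowest set bit
      break;
    }
  }
  const int B = (int)trees.size();
  std::unordered_map<uint64_t, int> tally;
  std::unordered_set<uint64_t> seen;
  BV x(nwords);
  for (const auto &rows : trees) {
    seen.clear();
    for (const BV &r : rows) {
      int ones = 0;
      for (int w = 0; w < nwords; ++w) {
        x[w] = r[w] & mask[w];
        ones += __builtin_popcountll(x[w]);
      }
      if (ones < 2 || m - ones < 2) continue;  // trivial after restriction
      if (x[fw] & fb)
        for (int w = 0; w < nwords; ++w) x[w] = ~x[w] & mask[w];
      uint64_t h = 0;
      for (int w = 0; w < nwords; ++w) h = mix64(h ^ x[w]);
      seen.insert(h);
    }
    for (uint64_t k : seen) ++tally[k];
  }
  double s = 0.0;
  for (const auto &kv : tally)
    if (2 * kv.second > B) s += (double)kv.second / B;
  return s / (n0 - 3);
}

// [[Rcpp::export]]
double cpp_rbic_score(List bipmats, LogicalVector keep, int n0) {
  int nwords;
  auto trees = pack_trees(bipmats, n0, nwords);
  BV mask(nwords, 0);
  int m = 0;
  for (int c = 0; c < n0; ++c)
    if (keep[c]) {
      mask[c >> 6] |= (uint64_t)1 << (c & 63);
      ++m;
    }
  return score_masked(trees, mask, m, n0, nwords);
}

// Score after additionally dropping each kept leaf in turn (NA elsewhere).
// [[Rcpp::export]]
NumericVector cpp_rbic_drop_scores(List bipmats, LogicalVector keep, int n0) {
  int nwords;
  auto trees = pack_trees(bipmats, n0, nwords);
  BV mask(nwords, 0);
  int m = 0;
  for (int c = 0; c < n0; ++c)
    if (keep[c]) {
      mask[c >> 6] |= (uint64_t)1 << (c & 63);
      ++m;
    }
  NumericVector out(n0, NA_REAL);
  for (int c = 0; c < n0; ++c) {
    if (!keep[c]) continue;
    BV mk = mask;
    mk[c >> 6] &= ~((uint64_t)1 << (c & 63));
    out[c] = score_masked(trees, mk, m - 1, n0, nwords);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
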