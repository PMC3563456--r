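#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weight lookup for RNA bases. Returns 0 when the two bases cannot pair.
static inline double pair_weight(char a, char b, double wGC, double wAU,
                                 double wGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return wGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return wAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return wGU;
  return 0.0;
}

// Maximum-weight nested pairing (Nussinov-style DP) with traceback.
//
// Recurrence over subsequence [i, j]:
//   M[i][j] = max( M[i+1][j],                              i unpaired
//                  max_k w(i,k) + M[i+1][k-1] + M[k+1][j] ) i paired to k
// subject to k - i - 1 >= min_loop and w(i,k) > 0.
//
// Tie-break in traceback: pairing i is preferred over leaving it unpaired,
// and the smallest admissible k is preferred — so the leftmost base is paired
// first, to its nearest partner, giving a bit-stable structure.
// [[Rcpp::export]]
List fold_dp(std::string seq, int min_loop, double wGC, double wAU,
             double wGU) {
  const int n = (int)seq.size();
  std::vector<std::vector<double> > M(n + 2, std::vector<double>(n + 2, 0.0));

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = pair_weight(seq[i - 1], seq[k - 1], wGC, wAU, wGU);
        if (w <= 0.0) continue;
        double inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0.0;
        double outer = (k + 1 <= j) ? M[k + 1][j] : 0.0;
        double cand = w + inner + outer;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  // Traceback with an explicit stack of (i, j) intervals.
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(1, n));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double w = pair_weight(seq[i - 1], seq[k - 1], wGC, wAU, wGU);
      if (w <= 0.0) continue;
      double inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0.0;
      double outer = (k + 1 <= j) ? M[k + 1][j] : 0.0;
      if (w + inner + outer >= M[i][j] - eps) {
        pi.push_back(i);
        pj.push_back(k);
        // push right interval first so the left one is traced next (order of
        // emitted pairs is by increasing i)
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  double score = (n > 0) ? M[1][n] : 0.0;
  return List::create(_["score"] = score, _["i"] = wrap(pi), _["j"] = wrap(pj));
}

// Leftmost adapter-overlap position per read.
//
// For each read, scans positions p = 1..len: the prefix of `adapter` is
// aligned at p with overlap ov = min(adapter_len, len - p + 1); the read is
// deemed adapter-bearing at the leftmost p where ov >= min_overlap and the
// mismatch fraction over the overlap is <= max_mm_frac. Returns, per read,
// the 1-based position where the adapter starts, or 0 if none.
// [[Rcpp::export]]
IntegerVector trim_positions(CharacterVector reads, std::string adapter,
                             int min_overlap, double max_mm_frac) {
  const int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    const int len = (int)s.size();
    int hit = 0;
    for (int p = 1; p <= len; ++p) {
      int ov = std::min(alen, len - p + 1);
      if (ov < min_overlap) break;
      int mm = 0;
      int allowed = (int)std::floor(max_mm_frac * ov);
      for (int t = 0; t < ov; ++t) {
        if (s[p - 1 + t] != adapter[t]) {
          ++mm;
          if (mm > allowed) break;
        }
      }
      if (mm <= allowed) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Exhaustive one-strand scan: all 1-based start positions where the read
// matches the genome with at most max_mm substitutions, with early exit per
// position. Returns a two-column matrix (start, mismatches).
// [[Rcpp::export]]
IntegerMatrix scan_positions(std::string genome, std::string read,
                             int max_mm) {
  const int n = (int)genome.size(), m = (int)read.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int t = 0; t < m; ++t) {
      if (genome[s + t] != read[t]) {
        ++mm;
        if (mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { starts.push_back(s + 1); mms.push_back(mm); }
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (int q = 0; q < (int)starts.size(); ++q) {
    out(q, 0) = starts[q];
    out(q, 1) = mms[q];
  }
  return out;
}

// Hamming mismatch counts between one read and genome slices starting at the
// given 1-based positions (all slices of length read length, assumed in
// bounds). Used by the seed-and-verify mapper.
// [[Rcpp::export]]
IntegerVector hamming_at(std::string genome, std::string read,
                         IntegerVector starts) {
  const int m = (int)read.size();
  IntegerVector out(starts.size());
  for (int q = 0; q < starts.size(); ++q) {
    int s = starts[q] - 1;
    int mm = 0;
    for (int t = 0; t < m; ++t)
      if (genome[s + t] != read[t]) ++mm;
    out[q] = mm;
  }
  return out;
}
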