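#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Repeat-tract scanners. Sequences arrive as integer codes: A,C,G,T -> 0..3,
// every other character (IUPAC ambiguity codes) -> -1. Coordinates returned
// 1-based inclusive.

static inline bool unit_primitive(const int* u, int k) {
  for (int d = 1; d < k; ++d) {
    if (k % d != 0) continue;
    bool rep = true;
    for (int i = d; i < k && rep; ++i)
      if (u[i] != u[i % d]) rep = false;
    if (rep) return false;
  }
  return true;
}

struct Cand {
  int start; // 0-based
  int end;   // 0-based inclusive
  int mm;
  int len() const { return end - start + 1; }
};

// Maximal perfect runs for one motif size k: blocks of the match array
// m[p] = (s[p] == s[p-k], both unambiguous). Run span includes any trailing
// partial unit; iterations = floor(len/k).
static void perfect_runs(const std::vector<int>& s, int k, int min_rep,
                         std::vector<Cand>& out) {
  const int n = (int)s.size();
  if (n < min_rep * k) return;
  int p = k;
  while (p < n) {
    if (s[p] >= 0 && s[p] == s[p - k]) {
      int p1 = p;
      while (p < n && s[p] >= 0 && s[p] == s[p - k]) ++p;
      int p2 = p - 1;
      int start = p1 - k, end = p2;
      int len = end - start + 1;
      if (len / k >= min_rep) {
        bool ok = true;
        for (int i = 0; i < k && ok; ++i)
          if (s[start + i] < 0) ok = false;
        if (ok && unit_primitive(&s[start], k))
          out.push_back(Cand{start, end, 0});
      }
    } else {
      ++p;
    }
  }
}

// All valid imperfect candidates anchored at each start position for size k.
// Semantics (documented in the package vignette):
//  * consensus = the k-mer at the tract start (first unit exact, primitive,
//    unambiguous);
//  * every complete aligned unit and the trailing partial unit carry at most
//    `m` mismatches;
//  * a run of consecutive mismatched bases never exceeds m*k;
//  * first and last base of the tract match the consensus;
//  * 100*mismatches/len <= p; floor(len/k) >= min_rep.
static void imperfect_candidates(const std::vector<int>& s, int k, int min_rep,
                                 int m, double p, std::vector<Cand>& out) {
  const int n = (int)s.size();
  const int gap_limit = m * k;
  const int min_len = min_rep * k;
  for (int a = 0; a + k <= n; ++a) {
    const int* u = &s[a];
    bool ok = true;
    for (int i = 0; i < k && ok; ++i)
      if (u[i] < 0) ok = false;
    if (!ok || !unit_primitive(u, k)) continue;
    if (min_rep == 1)
      out.push_back(Cand{a, a + k - 1, 0});
    int M = 0, window_mm = 0, gap = 0;
    for (int x = a + k; x < n; ++x) {
      int off = (x - a) % k;
      if (off == 0) window_mm = 0;
      bool match = (s[x] == u[off]); // ambiguity codes never match
      if (match) {
        gap = 0;
      } else {
        ++M;
        ++window_mm;
        ++gap;
        if (window_mm > m || gap > gap_limit) break;
      }
      int len = x - a + 1;
      if (match && len >= min_len && 100.0 * M <= p * len)
        out.push_back(Cand{a, x, M});
    }
  }
}

// Greedy resolution of same-size candidates: longest first, ties to the
// leftmost start; a candidate is discarded only when its span is contained
// in an already selected tract of the same size.
static void select_candidates(std::vector<Cand>& cands, std::vector<Cand>& kept) {
  std::sort(cands.begin(), cands.end(), [](const Cand& x, const Cand& y) {
    if (x.len() != y.len()) return x.len() > y.len();
    return x.start < y.start;
  });
  std::map<int, int> sel; // start -> end
  int max_len = 0;
  for (const Cand& c : cands) {
    bool contained = false;
    if (!sel.empty()) {
      auto it = sel.upper_bound(c.start);
      while (it != sel.begin()) {
        --it;
        if (it->first < c.start - max_len + 1) break;
        if (it->second >= c.end) { contained = true; break; }
      }
    }
    if (!contained) {
      sel[c.start] = c.end;
      kept.push_back(c);
      if (c.len() > max_len) max_len = c.len();
    }
  }
}

static DataFrame cands_to_df(const std::vector<Cand>& v,
                             const std::vector<int>& sizes_of) {
  int n = (int)v.size();
  IntegerVector start(n), end(n), size(n), mm(n);
  for (int i = 0; i < n; ++i) {
    start[i] = v[i].start + 1;
    end[i] = v[i].end + 1;
    size[i] = sizes_of[i];
    mm[i] = v[i].mm;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["size"] = size, _["mismatches"] = mm);
}

// [[Rcpp::export(name = ".scan_perfect_cpp")]]
DataFrame scan_perfect_cpp(IntegerVector seq, IntegerVector sizes,
                           IntegerVector min_repeats) {
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<Cand> all;
  std::vector<int> sz;
  for (int k : sizes) {
    std::vector<Cand> runs;
    perfect_runs(s, k, min_repeats[k - 1], runs);
    for (const Cand& c : runs) { all.push_back(c); sz.push_back(k); }
  }
  return cands_to_df(all, sz);
}

// [[Rcpp::export(name = ".scan_imperfect_cpp")]]
DataFrame scan_imperfect_cpp(IntegerVector seq, IntegerVector sizes,
                             IntegerVector min_repeats,
                             IntegerVector mismatch_limit,
                             NumericVector imperfection_pct) {
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<Cand> all;
  std::vector<int> sz;
  for (int k : sizes) {
    std::vector<Cand> cands, kept;
    imperfect_candidates(s, k, min_repeats[k - 1], mismatch_limit[k - 1],
                         imperfection_pct[k - 1], cands);
    select_candidates(cands, kept);
    for (const Cand& c : kept) { all.push_back(c); sz.push_back(k); }
  }
  return cands_to_df(all, sz);
}
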