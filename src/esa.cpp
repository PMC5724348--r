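// Enhanced suffix array machinery for k-mismatch common substring spectra.
//
// The text is the concatenation enc(s1) + SEP + enc(s2) over an integer
// alphabet.  SEP occurs exactly once, so no longest-common-prefix can span
// it.  In "mask" mode every non-ACGT character is given a code unique to its
// position, so masked characters never match anything (including another
// masked character, matching the treatment of N and ambiguity codes); in
// literal mode characters match byte-for-byte.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int SEP = 1;        // unique separator code
static const int BASE0 = 2;      // A,C,G,T -> 2..5
static const int UNIQ0 = 6;      // first code for masked / literal characters

// ---- encoding -------------------------------------------------------------

static void encode_seq(const std::string& s, std::vector<int>& out,
                       bool mask, int uniq_start) {
  int u = uniq_start;
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    int code;
    switch (c) {
    case 'A': case 'a': code = BASE0 + 0; break;
    case 'C': case 'c': code = BASE0 + 1; break;
    case 'G': case 'g': code = BASE0 + 2; break;
    case 'T': case 't': code = BASE0 + 3; break;
    default:
      if (mask) code = u++;                      // never matches anything
      else code = UNIQ0 + 256 + (unsigned char)c; // literal byte matching
    }
    out.push_back(code);
  }
}

struct Text {
  std::vector<int> t;   // concatenated encoded text
  int n1, n2;           // sequence lengths
  // global position of local (0-based) position in s1 / s2
  int g1(int i) const { return i; }
  int g2(int j) const { return n1 + 1 + j; }
  bool in_s1(int g) const { return g < n1; }
  bool in_s2(int g) const { return g > n1; }
  int loc2(int g) const { return g - n1 - 1; }
};

static Text make_text(const std::string& s1, const std::string& s2, bool mask) {
  Text tx;
  tx.n1 = (int)s1.size();
  tx.n2 = (int)s2.size();
  tx.t.reserve(tx.n1 + tx.n2 + 1);
  encode_seq(s1, tx.t, mask, UNIQ0 + 512);
  tx.t.push_back(SEP);
  encode_seq(s2, tx.t, mask, UNIQ0 + 512 + tx.n1);
  return tx;
}

// ---- suffix array (prefix doubling, radix sort) + Kasai LCP ---------------

static std::vector<int> suffix_array_int(const std::vector<int>& text) {
  std::vector<int> s(text);
  s.push_back(0);                                  // sentinel, smallest
  const int n = (int)s.size();
  // compress alphabet to 0..K-1 to keep counting arrays small
  {
    std::vector<int> vals(s);
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    for (int i = 0; i < n; ++i)
      s[i] = (int)(std::lower_bound(vals.begin(), vals.end(), s[i]) - vals.begin());
  }
  std::vector<int> sa(n), rnk(s), tmp(n), nr(n);
  std::vector<int> cnt(std::max(n, (int)(*std::max_element(s.begin(), s.end()) + 1)) + 1);

  std::iota(sa.begin(), sa.end(), 0);
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int i = 0; i < n; ++i) cnt[rnk[i]]++;
  for (size_t i = 1; i < cnt.size(); ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[rnk[i]]] = i;

  for (int len = 1; len < n; len <<= 1) {
    int idx = 0;
    for (int i = n - len; i < n; ++i) tmp[idx++] = i;
    for (int i = 0; i < n; ++i) if (sa[i] >= len) tmp[idx++] = sa[i] - len;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[rnk[i]]++;
    for (size_t i = 1; i < cnt.size(); ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[rnk[tmp[i]]]] = tmp[i];

    nr[sa[0]] = 0;
    int r = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      int a2 = a + len < n ? rnk[a + len] : -1;
      int b2 = b + len < n ? rnk[b + len] : -1;
      nr[b] = (rnk[a] == rnk[b] && a2 == b2) ? r : ++r;
    }
    rnk.swap(nr);
    if (r == n - 1) break;
  }
  sa.erase(sa.begin());                            // drop sentinel suffix
  return sa;
}

static std::vector<int> lcp_kasai(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  const int n = (int)sa.size();
  std::vector<int> rnk(n), lcp(n, 0);              // lcp[r] = lcp(sa[r-1], sa[r])
  for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rnk[i]] = h;
      if (h) --h;
    } else h = 0;
  }
  return lcp;
}

struct Esa {
  Text tx;
  std::vector<int> sa, lcp, rnk;
};

static Esa build_esa(const std::string& s1, const std::string& s2, bool mask) {
  Esa e;
  e.tx = make_text(s1, s2, mask);
  e.sa = suffix_array_int(e.tx.t);
  e.lcp = lcp_kasai(e.tx.t, e.sa);
  e.rnk.resize(e.sa.size());
  for (size_t i = 0; i < e.sa.size(); ++i) e.rnk[e.sa[i]] = (int)i;
  return e;
}

// ---- matching statistics --------------------------------------------------

// Longest match of the suffix at global position g against suffixes of the
// *other* sequence: walk up and down from rank of g until the first
// other-sequence entry, tracking the minimum LCP; X = max of the two minima.
static int longest_match_at(const Esa& e, int g, bool query_is_s2) {
  const int n = (int)e.sa.size();
  const int r = e.rnk[g];
  int up = 0, down = 0, mn;
  mn = INT32_MAX;
  for (int r2 = r - 1; r2 >= 0; --r2) {
    mn = std::min(mn, e.lcp[r2 + 1]);
    if (mn == 0) break;
    int o = e.sa[r2];
    if (query_is_s2 ? e.tx.in_s1(o) : e.tx.in_s2(o)) { up = mn; break; }
  }
  mn = INT32_MAX;
  for (int r2 = r + 1; r2 < n; ++r2) {
    mn = std::min(mn, e.lcp[r2]);
    if (mn == 0) break;
    int o = e.sa[r2];
    if (query_is_s2 ? e.tx.in_s1(o) : e.tx.in_s2(o)) { down = mn; break; }
  }
  return std::max(up, down);
}

// All start positions (global) in the other sequence achieving match length X:
// continue in both directions while the running LCP minimum stays >= X.
static void partners_at(const Esa& e, int g, int X, bool query_is_s2,
                        std::vector<int>& out) {
  out.clear();
  if (X <= 0) return;
  const int n = (int)e.sa.size();
  const int r = e.rnk[g];
  int mn = INT32_MAX;
  for (int r2 = r - 1; r2 >= 0; --r2) {
    mn = std::min(mn, e.lcp[r2 + 1]);
    if (mn < X) break;
    int o = e.sa[r2];
    if (query_is_s2 ? e.tx.in_s1(o) : e.tx.in_s2(o)) out.push_back(o);
  }
  mn = INT32_MAX;
  for (int r2 = r + 1; r2 < n; ++r2) {
    mn = std::min(mn, e.lcp[r2]);
    if (mn < X) break;
    int o = e.sa[r2];
    if (query_is_s2 ? e.tx.in_s1(o) : e.tx.in_s2(o)) out.push_back(o);
  }
}

// ---- k-mismatch extension -------------------------------------------------

// Maximal length l such that the substrings of length l at (a, b) (local
// 0-based coordinates in s1/s2) contain exactly k mismatches, i.e. the scan
// stops just before the (k+1)-st mismatch.  If a sequence end is reached
// first the observed length is returned and *trunc is set.
static int extension_length(const Text& tx, int a, int b, int k, bool* trunc) {
  if (a < 0 || b < 0 || a >= tx.n1 || b >= tx.n2) { *trunc = true; return 0; }
  const int* A = tx.t.data();
  const int* B = tx.t.data() + tx.n1 + 1;
  int mism = 0, l = 0;
  const int maxl = std::min(tx.n1 - a, tx.n2 - b);
  while (l < maxl) {
    if (A[a + l] != B[b + l]) {
      if (mism == k) { *trunc = false; return l; }
      ++mism;
    }
    ++l;
  }
  *trunc = true;
  return l;
}

// ---- exported interfaces --------------------------------------------------

// [[Rcpp::export]]
List cpp_matching_stats(std::string s1, std::string s2, bool query_second,
                        bool mask) {
  Esa e = build_esa(s1, s2, mask);
  const int nq = query_second ? e.tx.n2 : e.tx.n1;
  IntegerVector X(nq);
  List partners(nq);
  std::vector<int> ps;
  for (int i = 0; i < nq; ++i) {
    int g = query_second ? e.tx.g2(i) : e.tx.g1(i);
    int x = longest_match_at(e, g, query_second);
    X[i] = x;
    partners_at(e, g, x, query_second, ps);
    IntegerVector pv((int)ps.size());
    for (size_t t = 0; t < ps.size(); ++t) {
      int o = ps[t];
      pv[t] = (query_second ? o : e.tx.loc2(o)) + 1;  // 1-based local
    }
    std::sort(pv.begin(), pv.end());
    partners[i] = pv;
  }
  return List::create(_["x"] = X, _["partners"] = partners);
}

// [[Rcpp::export]]
List cpp_extension(std::string s1, std::string s2, int i_start, int j_start,
                   int k, bool mask) {
  Text tx = make_text(s1, s2, mask);
  bool tr = false;
  int l = extension_length(tx, i_start, j_start, k, &tr);
  return List::create(_["length"] = l, _["truncated"] = tr);
}

// One direction of the spectrum: every query position i, every partner j*;
// each distinct extension start (i', j') = (i + X + 1, j* + X + 1) counted
// once.  counts is indexed by extension length (offset 0).
static void spectrum_direction(const Esa& e, bool query_is_s2, int k,
                               bool dedup, std::vector<int64_t>& counts,
                               int64_t* n_ext, int64_t* n_trunc) {
  const Text& tx = e.tx;
  const int nq = query_is_s2 ? tx.n2 : tx.n1;
  std::unordered_set<int64_t> seen;
  std::vector<int> ps;
  for (int i = 0; i < nq; ++i) {
    int g = query_is_s2 ? tx.g2(i) : tx.g1(i);
    int X = longest_match_at(e, g, query_is_s2);
    if (X <= 0) continue;
    partners_at(e, g, X, query_is_s2, ps);
    for (size_t t = 0; t < ps.size(); ++t) {
      int jloc = query_is_s2 ? ps[t] : tx.loc2(ps[t]);
      // local coords of extension start in (s1, s2) order
      int a = query_is_s2 ? jloc + X + 1 : i + X + 1;
      int b = query_is_s2 ? i + X + 1 : jloc + X + 1;
      // no room for an extension: the exact match ran to a sequence end,
      // so there is no first mismatch to extend after
      if (a >= tx.n1 || b >= tx.n2) continue;
      if (dedup) {
        int64_t key = (int64_t)a * (tx.n2 + 2) + b;
        if (!seen.insert(key).second) continue;
      }
      bool tr = false;
      int l = extension_length(tx, a, b, k, &tr);
      if ((size_t)l >= counts.size()) counts.resize(l + 1, 0);
      counts[l]++;
      (*n_ext)++;
      if (tr) (*n_trunc)++;
    }
  }
}

// [[Rcpp::export]]
List cpp_spectrum(std::string s1, std::string s2, int k, bool pool,
                  bool mask, bool dedup) {
  Esa e = build_esa(s1, s2, mask);
  std::vector<int64_t> counts;
  int64_t n_ext = 0, n_trunc = 0;
  spectrum_direction(e, false, k, dedup, counts, &n_ext, &n_trunc);
  if (pool)
    spectrum_direction(e, true, k, dedup, counts, &n_ext, &n_trunc);
  NumericVector cv((int)counts.size());
  for (size_t i = 0; i < counts.size(); ++i) cv[i] = (double)counts[i];
  return List::create(_["counts"] = cv,
                      _["n_extensions"] = (double)n_ext,
                      _["n_truncated"] = (double)n_trunc);
}

// Per-position heuristic records for one query direction (s1 as query):
// X_i, the selected partner j*, the k-mismatch extension length after the
// first mismatch (Eq.-17 variable), and the full heuristic hit length
// X_i + 1 + (k-1)-mismatch extension (Theorem-1 variable).  Tie convention:
// tie_hom selects the homologous partner whenever it attains X_i; otherwise
// a background partner is preferred when one exists.
// [[Rcpp::export]]
DataFrame cpp_per_position(std::string s1, std::string s2, int k, bool mask,
                           bool tie_hom) {
  Esa e = build_esa(s1, s2, mask);
  const Text& tx = e.tx;
  const int nq = tx.n1;
  IntegerVector X(nq), jstar(nq), ext(nq), hit(nq);
  LogicalVector homol(nq), ext_trunc(nq), hit_trunc(nq), has(nq);
  std::vector<int> ps;
  for (int i = 0; i < nq; ++i) {
    int X_i = longest_match_at(e, i, false);
    X[i] = X_i;
    if (X_i <= 0) { has[i] = false; continue; }
    partners_at(e, i, X_i, false, ps);
    if (ps.empty()) { has[i] = false; continue; }
    has[i] = true;
    bool have_hom = false, have_bg = false;
    int bg = -1;
    for (size_t t = 0; t < ps.size(); ++t) {
      int jl = tx.loc2(ps[t]);
      if (jl == i) have_hom = true;
      else if (bg < 0) { have_bg = true; bg = jl; }
    }
    int j;
    if (tie_hom) j = have_hom ? i : bg;
    else         j = have_bg ? bg : i;
    jstar[i] = j + 1;                      // 1-based
    homol[i] = (j == i);
    bool tr = false;
    ext[i] = extension_length(tx, i + X_i + 1, j + X_i + 1, k, &tr);
    ext_trunc[i] = tr;
    if (k >= 1) {
      bool tr2 = false;
      int e2 = extension_length(tx, i + X_i + 1, j + X_i + 1, k - 1, &tr2);
      // hit is truncated if the exact match already reached an end
      bool match_trunc = (i + X_i >= tx.n1) || (j + X_i >= tx.n2);
      hit[i] = X_i + 1 + e2;
      hit_trunc[i] = tr2 || match_trunc;
      if (match_trunc) hit[i] = X_i;       // no first mismatch observed
    } else {
      hit[i] = NA_INTEGER;
      hit_trunc[i] = true;
    }
  }
  return DataFrame::create(_["x"] = X, _["jstar"] = jstar,
                           _["homologous"] = homol, _["ext"] = ext,
                           _["ext_truncated"] = ext_trunc, _["hit"] = hit,
                           _["hit_truncated"] = hit_trunc, _["valid"] = has);
}

// Naive O(L^2) longest k-mismatch match per query position of s1 (test
// oracle for the closed-form law of X_i^(k); also used with k = 0).
// [[Rcpp::export]]
IntegerVector cpp_naive_kmismatch_longest(std::string s1, std::string s2,
                                          int k, bool mask) {
  Text tx = make_text(s1, s2, mask);
  IntegerVector X(tx.n1);
  for (int i = 0; i < tx.n1; ++i) {
    int best = 0;
    for (int j = 0; j < tx.n2; ++j) {
      bool tr = false;
      int l = extension_length(tx, i, j, k, &tr);
      if (l > best) best = l;
    }
    X[i] = best;
  }
  return X;
}
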