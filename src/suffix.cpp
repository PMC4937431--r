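// Suffix-array engine for k-mer spectra and maximal repeat length.
//
// The genome's unambiguous runs are joined with a separator symbol and a
// terminal sentinel; the suffix array is built with SA-IS (linear time,
// integer alphabet) and the LCP array with Kasai's algorithm.  LCP values
// are capped at the "valid length" of each suffix (distance to the next
// separator/sentinel) so that no repeated word or k-mer ever spans a run
// boundary.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstring>

using namespace Rcpp;

// symbol coding: 0 = terminal sentinel, 1 = run separator, 2..5 = a,c,g,t
static const int SENTINEL = 0;
static const int SEP = 1;
static const int ALPHA_MAX = 5;

static inline bool isLMS(const std::vector<bool>& t, int i) {
  return i > 0 && t[i] && !t[i - 1];
}

static void getBuckets(const int* s, int n, int K, int* bkt, bool end) {
  for (int i = 0; i <= K; i++) bkt[i] = 0;
  for (int i = 0; i < n; i++) bkt[s[i]]++;
  int sum = 0;
  for (int i = 0; i <= K; i++) { sum += bkt[i]; bkt[i] = end ? sum : sum - bkt[i]; }
}

static void induceSAl(const std::vector<bool>& t, int* SA, const int* s,
                      int* bkt, int n, int K) {
  getBuckets(s, n, K, bkt, false);
  for (int i = 0; i < n; i++) {
    int j = SA[i];
    if (j > 0 && !t[j - 1]) SA[bkt[s[j - 1]]++] = j - 1;
  }
}

static void induceSAs(const std::vector<bool>& t, int* SA, const int* s,
                      int* bkt, int n, int K) {
  getBuckets(s, n, K, bkt, true);
  for (int i = n - 1; i >= 0; i--) {
    int j = SA[i];
    if (j > 0 && t[j - 1]) SA[--bkt[s[j - 1]]] = j - 1;
  }
}

// s[0..n-1] with s[n-1] == 0 the unique minimal sentinel; symbols in [0, K].
static void saisMain(const int* s, int* SA, int n, int K) {
  if (n == 1) { SA[0] = 0; return; }
  if (n == 2) { SA[0] = 1; SA[1] = 0; return; }
  std::vector<bool> t(n);
  t[n - 1] = true;
  t[n - 2] = false;
  for (int i = n - 3; i >= 0; i--)
    t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);

  std::vector<int> bkt(K + 1);
  getBuckets(s, n, K, bkt.data(), true);
  for (int i = 0; i < n; i++) SA[i] = -1;
  for (int i = 1; i < n; i++)
    if (isLMS(t, i)) SA[--bkt[s[i]]] = i;
  induceSAl(t, SA, s, bkt.data(), n, K);
  induceSAs(t, SA, s, bkt.data(), n, K);

  int n1 = 0;
  for (int i = 0; i < n; i++)
    if (isLMS(t, SA[i])) SA[n1++] = SA[i];
  for (int i = n1; i < n; i++) SA[i] = -1;

  // name sorted LMS substrings
  int name = 0, prev = -1;
  for (int i = 0; i < n1; i++) {
    int pos = SA[i];
    bool diff = false;
    for (int d = 0; d < n; d++) {
      if (prev == -1 || s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
        diff = true; break;
      } else if (d > 0 && (isLMS(t, pos + d) || isLMS(t, prev + d))) {
        break;
      }
    }
    if (diff) { name++; prev = pos; }
    SA[n1 + pos / 2] = name - 1;
  }
  for (int i = n - 1, j = n - 1; i >= n1; i--)
    if (SA[i] >= 0) SA[j--] = SA[i];

  int* SA1 = SA;
  int* s1 = SA + n - n1;
  if (name < n1) {
    saisMain(s1, SA1, n1, name - 1);
  } else {
    for (int i = 0; i < n1; i++) SA1[s1[i]] = i;
  }

  for (int i = 1, j = 0; i < n; i++)
    if (isLMS(t, i)) s1[j++] = i;
  for (int i = 0; i < n1; i++) SA1[i] = s1[SA1[i]];
  for (int i = n1; i < n; i++) SA[i] = -1;
  getBuckets(s, n, K, bkt.data(), true);
  for (int i = n1 - 1; i >= 0; i--) {
    int j = SA[i]; SA[i] = -1;
    SA[--bkt[s[j]]] = j;
  }
  induceSAl(t, SA, s, bkt.data(), n, K);
  induceSAs(t, SA, s, bkt.data(), n, K);
}

// encode runs (lowercase acgt strings) into the joined symbol text
static std::vector<int> encodeRuns(const CharacterVector& runs) {
  long long total = 0;
  for (R_xlen_t r = 0; r < runs.size(); r++) total += LENGTH(STRING_ELT(runs, r));
  total += runs.size();  // separators between runs + final sentinel
  if (total > INT_MAX - 2)
    stop("genome too large for the 32-bit suffix array index");
  std::vector<int> s;
  s.reserve((size_t)total);
  for (R_xlen_t r = 0; r < runs.size(); r++) {
    SEXP str = STRING_ELT(runs, r);
    const char* p = CHAR(str);
    int len = LENGTH(str);
    if (r > 0) s.push_back(SEP);
    for (int i = 0; i < len; i++) {
      int code;
      switch (p[i]) {
        case 'a': code = 2; break;
        case 'c': code = 3; break;
        case 'g': code = 4; break;
        case 't': code = 5; break;
        default: stop("runs must contain only lowercase a, c, g, t");
      }
      s.push_back(code);
    }
  }
  s.push_back(SENTINEL);
  return s;
}

// valid[i]: number of consecutive nucleotide symbols starting at i
static std::vector<int> validLengths(const std::vector<int>& s) {
  int n = (int)s.size();
  std::vector<int> valid(n);
  valid[n - 1] = 0;
  for (int i = n - 2; i >= 0; i--)
    valid[i] = (s[i] >= 2) ? valid[i + 1] + 1 : 0;
  return valid;
}

// Kasai LCP; lcp[i] = lcp(suffix SA[i-1], suffix SA[i]), lcp[0] = 0
static void kasai(const std::vector<int>& s, const std::vector<int>& sa,
                  std::vector<int>& lcp) {
  int n = (int)s.size();
  std::vector<int> rank(n);
  for (int i = 0; i < n; i++) rank[sa[i]] = i;
  lcp.assign(n, 0);
  int h = 0;
  for (int i = 0; i < n; i++) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) h++;
      lcp[rank[i]] = h;
      if (h > 0) h--;
    } else {
      h = 0;
    }
  }
}

// [[Rcpp::export(name = ".cppBuildSuffix")]]
List cppBuildSuffix(CharacterVector runs) {
  std::vector<int> s = encodeRuns(runs);
  int n = (int)s.size();
  std::vector<int> sa(n);
  saisMain(s.data(), sa.data(), n, ALPHA_MAX);
  std::vector<int> lcp;
  kasai(s, sa, lcp);
  std::vector<int> valid = validLengths(s);
  // cap LCPs so that common prefixes never cross run boundaries
  IntegerVector saOut(n), lcpOut(n), validOut(n);
  for (int i = 0; i < n; i++) {
    saOut[i] = sa[i];
    validOut[i] = valid[sa[i]];  // valid length in suffix-array order
    int c = lcp[i];
    if (i > 0) {
      if (validOut[i] < c) c = validOut[i];
      if (validOut[i - 1] < c) c = validOut[i - 1];
    } else {
      c = 0;
    }
    lcpOut[i] = c;
  }
  return List::create(_["sa"] = saOut, _["lcp"] = lcpOut,
                      _["valid"] = validOut, _["textLength"] = n);
}

// k-mer spectrum by scanning suffix-array groups at prefix depth k.
// Returns distinct, occurrences, and the multiplicity histogram.
// [[Rcpp::export(name = ".cppSpectrum")]]
List cppSpectrum(IntegerVector sa, IntegerVector lcp, IntegerVector valid, int k) {
  int n = sa.size();
  long long distinct = 0, occurrences = 0;
  std::map<long long, long long> hist;
  long long group = 0;
  for (int i = 0; i < n; i++) {
    if (i > 0 && lcp[i] < k && group > 0) {
      distinct++; occurrences += group; hist[group]++;
      group = 0;
    }
    if (valid[i] >= k) group++;
  }
  if (group > 0) { distinct++; occurrences += group; hist[group]++; }
  int m = (int)hist.size();
  NumericVector mult(m), count(m);
  int idx = 0;
  for (std::map<long long, long long>::iterator it = hist.begin();
       it != hist.end(); ++it) {
    mult[idx] = (double)it->first;
    count[idx] = (double)it->second;
    idx++;
  }
  return List::create(_["distinct"] = (double)distinct,
                      _["occurrences"] = (double)occurrences,
                      _["multiplicity"] = mult, _["count"] = count);
}

// maximal repeat length = max capped LCP
// [[Rcpp::export(name = ".cppMaxLcp")]]
int cppMaxLcp(IntegerVector lcp) {
  int n = lcp.size(), m = 0;
  for (int i = 0; i < n; i++) if (lcp[i] > m) m = lcp[i];
  return m;
}

// one-shot mrl for a single-run genome given as integer codes 1..4
// (fast path for random-genome trials; avoids string materialization)
// [[Rcpp::export(name = ".cppMrlCodes")]]
int cppMrlCodes(IntegerVector codes) {
  int n0 = codes.size();
  if (n0 < 1) stop("empty code vector");
  std::vector<int> s(n0 + 1);
  for (int i = 0; i < n0; i++) {
    int c = codes[i];
    if (c < 1 || c > 4) stop("codes must lie in 1..4");
    s[i] = c + 1;  // shift into 2..5, keep 0 for the sentinel
  }
  s[n0] = SENTINEL;
  int n = n0 + 1;
  std::vector<int> sa(n);
  saisMain(s.data(), sa.data(), n, ALPHA_MAX);
  // streaming Kasai, tracking only the maximum
  std::vector<int> rank(n);
  for (int i = 0; i < n; i++) rank[sa[i]] = i;
  int h = 0, best = 0;
  for (int i = 0; i < n; i++) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) h++;
      if (h > best) best = h;
      if (h > 0) h--;
    } else {
      h = 0;
    }
  }
  return best;
}
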