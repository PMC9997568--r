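#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Global alignment under unit edit costs (mismatch = 1, gap = 1), with a
// lexicographic objective: minimise total edits, and among minimum-edit
// alignments maximise the number of matched columns.  The match count is
// what the identity metric (matches / shorter length) is defined on.
//
// Both objectives are packed into one integer, v = edits * K - matches with
// K larger than any possible match count, so the lexicographic optimum is a
// plain minimum and the inner loop is a 3-way min.  Sequences are limited to
// K - 1 bases.
//
// The banded variant restricts the path to |i - j| <= band.  Any alignment
// with e total edits satisfies |i - j| <= e at every point of its path, so
// if the caller chooses band >= 2*m*(1-c) + |len(a)-len(b)| the banded
// result is exact whenever identity >= c, and a returned edit count above
// the band proves identity < c (see greedy_cluster()).

static const int K = 8192;           // packing radix; max supported length K-1
static const int BIG = INT_MAX / 4;

static inline int unpack_edits(int v) { return (v + K - 1) / K; }
static inline int unpack_matches(int v) { return unpack_edits(v) * K - v; }

// [[Rcpp::export]]
IntegerVector cpp_align_stats(std::string a, std::string b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if (m >= K || n >= K) stop("sequence longer than supported maximum");
  const bool banded = band >= 0;

  std::vector<int> V(n + 1), Vp(n + 1);
  for (int j = 0; j <= n; ++j) Vp[j] = (!banded || j <= band) ? j * K : BIG;
  for (int i = 1; i <= m; ++i) {
    const int lo = banded ? std::max(1, i - band) : 1;
    const int hi = banded ? std::min(n, i + band) : n;
    for (int j = 0; j < lo; ++j) V[j] = BIG;
    if (lo == 1 && (!banded || i <= band)) V[0] = i * K;
    for (int j = hi + 1; j <= n; ++j) V[j] = BIG;
    const char ai = a[i - 1];
    int rowmin = V[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int v = Vp[j - 1] + (ai == b[j - 1] ? -1 : K); // diagonal
      const int vu = Vp[j] + K;                      // gap in b (consume a)
      if (vu < v) v = vu;
      const int vl = V[j - 1] + K;                   // gap in a (consume b)
      if (vl < v) v = vl;
      V[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (banded && (rowmin >= BIG || unpack_edits(rowmin) > band)) {
      return IntegerVector::create(-1, -1);
    }
    std::swap(V, Vp);
  }
  const int v = Vp[n];
  if (v >= BIG || (banded && unpack_edits(v) > band))
    return IntegerVector::create(-1, -1);
  return IntegerVector::create(unpack_edits(v), unpack_matches(v));
}

// Full-matrix variant returning the aligned strings ('-' for gaps) under the
// same objective, with a deterministic tie preference diagonal > up > left.
// [[Rcpp::export]]
CharacterVector cpp_align_strings(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if (m >= K || n >= K) stop("sequence longer than supported maximum");

  std::vector<int> V(n + 1), Vp(n + 1);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1)); // 0 diag, 1 up, 2 left
  for (int j = 0; j <= n; ++j) { Vp[j] = j * K; tb[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    V[0] = i * K;
    unsigned char* tbi = &tb[(size_t)i * (n + 1)];
    tbi[0] = 1;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      int v = Vp[j - 1] + (ai == b[j - 1] ? -1 : K);
      unsigned char t = 0;
      if (Vp[j] + K < v) { v = Vp[j] + K; t = 1; }
      if (V[j - 1] + K < v) { v = V[j - 1] + K; t = 2; }
      V[j] = v;
      tbi[j] = t;
    }
    std::swap(V, Vp);
  }
  std::string ra, rb;
  ra.reserve(m + n); rb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (i > 0 && j > 0 && t == 0) { ra += a[--i]; rb += b[--j]; }
    else if (i > 0 && (t == 1 || j == 0)) { ra += a[--i]; rb += '-'; }
    else { ra += '-'; rb += b[--j]; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return CharacterVector::create(ra, rb);
}
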