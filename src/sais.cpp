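#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>

// Induced-sorting (SA-IS) suffix array construction over an integer
// sequence whose last element is the unique minimum (the terminator).
// Values must lie in [0, K); one bucket-count array of K words is
// allocated per recursion level, mirroring the sigma^k bucket term of
// induced sorting over a packed (transformed) alphabet.
//
// Top level uses 64-bit values because packed k-mer blocks can exceed
// 32 bits; recursion levels use 32-bit names (< n/2). Positions are
// 0-based and returned as a 32-bit permutation, so n < 2^31.

namespace {

template <typename T>
void get_buckets(const T* s, std::vector<int32_t>& bkt, int64_t n,
                 int64_t K, bool end) {
  std::fill(bkt.begin(), bkt.end(), 0);
  for (int64_t i = 0; i < n; ++i) bkt[s[i]]++;
  int32_t sum = 0;
  for (int64_t i = 0; i < K; ++i) {
    sum += bkt[i];
    bkt[i] = end ? sum : sum - bkt[i];
  }
}

template <typename T>
void induce_l(const std::vector<uint8_t>& t, int32_t* SA, const T* s,
              std::vector<int32_t>& bkt, int64_t n, int64_t K) {
  get_buckets(s, bkt, n, K, false);
  for (int64_t i = 0; i < n; ++i) {
    int32_t j = SA[i] - 1;
    if (SA[i] > 0 && !t[j]) SA[bkt[s[j]]++] = j;
  }
}

template <typename T>
void induce_s(const std::vector<uint8_t>& t, int32_t* SA, const T* s,
              std::vector<int32_t>& bkt, int64_t n, int64_t K) {
  get_buckets(s, bkt, n, K, true);
  for (int64_t i = n - 1; i >= 0; --i) {
    int32_t j = SA[i] - 1;
    if (SA[i] > 0 && t[j]) SA[--bkt[s[j]]] = j;
  }
}

template <typename T>
void sais_core(const T* s, int32_t* SA, int64_t n, int64_t K) {
  if (n == 1) { SA[0] = 0; return; }

  // L/S type classification; the terminator is S by convention and,
  // being the unique minimum, forces t[n-2] = L.
  std::vector<uint8_t> t(n);
  t[n - 1] = 1;
  t[n - 2] = 0;
  for (int64_t i = n - 3; i >= 0; --i)
    t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);

  std::vector<int32_t> bkt(K);

  // Stage 1: place LMS suffixes at bucket ends, then induce L and S.
  get_buckets(s, bkt, n, K, true);
  std::fill(SA, SA + n, -1);
  for (int64_t i = 1; i < n; ++i)
    if (t[i] && !t[i - 1]) SA[--bkt[s[i]]] = (int32_t)i;
  induce_l(t, SA, s, bkt, n, K);
  induce_s(t, SA, s, bkt, n, K);

  // Compact the now-sorted LMS suffixes into SA[0..n1).
  int64_t n1 = 0;
  for (int64_t i = 0; i < n; ++i) {
    int32_t p = SA[i];
    if (p > 0 && t[p] && !t[p - 1]) SA[n1++] = p;
  }

  // Name LMS substrings; equal substrings share a name.
  std::fill(SA + n1, SA + n, -1);
  int64_t name = 0, prev = -1;
  for (int64_t i = 0; i < n1; ++i) {
    int64_t pos = SA[i];
    bool diff = false;
    for (int64_t d = 0; d < n; ++d) {
      if (prev == -1 || s[pos + d] != s[prev + d] ||
          t[pos + d] != t[prev + d]) {
        diff = true;
        break;
      }
      if (d > 0 && ((t[pos + d] && !t[pos + d - 1]) ||
                    (t[prev + d] && !t[prev + d - 1])))
        break;
    }
    if (diff) { name++; prev = pos; }
    SA[n1 + pos / 2] = (int32_t)(name - 1);
  }
  for (int64_t i = n - 1, j = n - 1; i >= n1; --i)
    if (SA[i] >= 0) SA[j--] = SA[i];

  // Recurse on the reduced problem if names are not yet unique.
  int32_t* SA1 = SA;
  int32_t* s1 = SA + n - n1;
  if (name < n1)
    sais_core<int32_t>(s1, SA1, n1, name);
  else
    for (int64_t i = 0; i < n1; ++i) SA1[s1[i]] = (int32_t)i;

  // Stage 3: map the reduced order back to LMS positions and induce
  // the full order from them.
  for (int64_t i = 1, j = 0; i < n; ++i)
    if (t[i] && !t[i - 1]) s1[j++] = (int32_t)i;
  for (int64_t i = 0; i < n1; ++i) SA1[i] = s1[SA1[i]];
  std::fill(SA + n1, SA + n, -1);
  get_buckets(s, bkt, n, K, true);
  for (int64_t i = n1 - 1; i >= 0; --i) {
    int32_t j = SA[i];
    SA[i] = -1;
    SA[--bkt[s[j]]] = j;
  }
  induce_l(t, SA, s, bkt, n, K);
  induce_s(t, SA, s, bkt, n, K);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector sais_cpp(Rcpp::NumericVector seq, double bound) {
  int64_t n = seq.size();
  int64_t K = (int64_t)bound;
  std::vector<int64_t> s(n);
  for (int64_t i = 0; i < n; ++i) s[i] = (int64_t)seq[i];
  Rcpp::IntegerVector out(n);
  sais_core<int64_t>(s.data(), (int32_t*)INTEGER(out), n, K);
  return out;
}
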