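#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Uniquely-mappable-position scan: a start position p is unique iff the
// k-mer starting at p occurs exactly once in the whole sequence set, counting
// both strands (forward key and reverse-complement key collapse to one
// canonical key). Implemented with a 64-bit polynomial rolling hash; distinct
// k-mers collide with probability ~ n^2 / 2^64, negligible at the genome
// sizes this package targets, and cross-checked elsewhere against an exact
// string-dictionary oracle. Windows containing non-ACGT bases are never
// unique by policy.

static const uint64_t HB = 0x9E3779B97F4A7C15ULL;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// rolling forward hashes of all k-mers of `code`; ok[p] = no invalid base in
// window p. out/ok must be pre-sized to n = L - k + 1.
static void fwd_hashes(const std::vector<int>& code, int k, uint64_t Bk,
                       std::vector<uint64_t>& out, std::vector<uint8_t>& ok) {
  long L = (long)code.size();
  long n = L - k + 1;
  if (n <= 0) return;
  uint64_t h = 0;
  int bad = 0;
  for (int i = 0; i < k; ++i) {
    int c = code[i];
    if (c < 0) { ++bad; c = 0; }
    h = h * HB + (uint64_t)c;
  }
  out[0] = h; ok[0] = (bad == 0);
  for (long p = 1; p < n; ++p) {
    int cout_ = code[p - 1];
    int cin_ = code[p + k - 1];
    if (cout_ < 0) { --bad; cout_ = 0; }
    if (cin_ < 0) { ++bad; cin_ = 0; }
    h = (h - (uint64_t)cout_ * Bk) * HB + (uint64_t)cin_;
    out[p] = h; ok[p] = (bad == 0);
  }
}

// [[Rcpp::export(name = ".kmer_unique_mask")]]
List kmer_unique_mask(CharacterVector seqs, int k, bool both_strands) {
  int nseq = seqs.size();
  if (k < 1) stop("k must be >= 1");
  uint64_t Bk = 1;
  for (int i = 0; i < k - 1; ++i) Bk *= HB;

  std::vector< std::vector<int> > codes(nseq);
  for (int s = 0; s < nseq; ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    long L = (long)LENGTH(STRING_ELT(seqs, s));
    codes[s].resize(L);
    for (long i = 0; i < L; ++i) codes[s][i] = base_code(str[i]);
  }

  std::unordered_map<uint64_t, uint32_t> counts;
  {
    long total = 0;
    for (int s = 0; s < nseq; ++s) {
      long n = (long)codes[s].size() - k + 1;
      if (n > 0) total += n;
    }
    counts.reserve((size_t)(total * 1.4) + 16);
  }

  // pass 1: count canonical keys of valid windows
  for (int s = 0; s < nseq; ++s) {
    long L = (long)codes[s].size();
    long n = L - k + 1;
    if (n <= 0) continue;
    std::vector<uint64_t> hf(n), hr;
    std::vector<uint8_t> okf(n), okr;
    fwd_hashes(codes[s], k, Bk, hf, okf);
    if (both_strands) {
      std::vector<int> rc(L);
      for (long i = 0; i < L; ++i) {
        int c = codes[s][L - 1 - i];
        rc[i] = (c < 0) ? -1 : 3 - c;
      }
      hr.resize(n); okr.resize(n);
      fwd_hashes(rc, k, Bk, hr, okr);
    }
    for (long p = 0; p < n; ++p) {
      if (!okf[p]) continue;
      uint64_t key = hf[p];
      if (both_strands) {
        uint64_t krc = hr[n - 1 - p];  // k-mer at p reverse-complements here
        if (krc < key) key = krc;
      }
      uint32_t& c = counts[key];
      if (c < 2) ++c;
    }
  }

  // pass 2: mark unique starts
  List masks(nseq);
  for (int s = 0; s < nseq; ++s) {
    long L = (long)codes[s].size();
    LogicalVector m(L, false);
    long n = L - k + 1;
    if (n > 0) {
      std::vector<uint64_t> hf(n), hr;
      std::vector<uint8_t> okf(n), okr;
      fwd_hashes(codes[s], k, Bk, hf, okf);
      if (both_strands) {
        std::vector<int> rc(L);
        for (long i = 0; i < L; ++i) {
          int c = codes[s][L - 1 - i];
          rc[i] = (c < 0) ? -1 : 3 - c;
        }
        hr.resize(n); okr.resize(n);
        fwd_hashes(rc, k, Bk, hr, okr);
      }
      for (long p = 0; p < n; ++p) {
        if (!okf[p]) continue;
        uint64_t key = hf[p];
        if (both_strands) {
          uint64_t krc = hr[n - 1 - p];
          if (krc < key) key = krc;
        }
        m[p] = (counts[key] == 1);
      }
    }
    masks[s] = m;
  }
  if (seqs.hasAttribute("names")) masks.names() = seqs.names();
  return masks;
}
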