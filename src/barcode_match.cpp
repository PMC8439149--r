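#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Assignment codes: >=1 barcode index (1-based), 0 none, -1 ambiguous,
// -2 invalid read (non-ACGTN character).

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N';
}

// Hamming mismatches between read[rstart..rstart+len) and bc[bstart..bstart+len).
// 'N' in the read never matches. Early exit past max_mm.
static inline int mismatches(const std::string& read, int rstart,
                             const std::string& bc, int bstart,
                             int len, int max_mm) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char r = read[rstart + i];
    if (r == 'N' || r != bc[bstart + i]) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// A barcode is a candidate for a read if
//  (a) its full sequence occurs anywhere in the read within max_mm, or
//  (b) a prefix of the barcode of length k aligns flush with the read's
//      3' end, or a suffix of length k flush with the 5' end, with
//      k strictly greater than min_frac * L, within max_mm.
static bool is_candidate(const std::string& read, const std::string& bc,
                         double min_frac, int max_mm) {
  const int n = (int)read.size();
  const int L = (int)bc.size();
  // full containment
  for (int o = 0; o + L <= n; ++o) {
    if (mismatches(read, o, bc, 0, L, max_mm) <= max_mm) return true;
  }
  const double thr = min_frac * (double)L;
  int kmax = std::min(L - 1, n);
  for (int k = kmax; k >= 1; --k) {
    if ((double)k <= thr + 1e-9) break;  // overlap must be strictly > thr
    // barcode prefix of length k at read 3' end
    if (mismatches(read, n - k, bc, 0, k, max_mm) <= max_mm) return true;
    // barcode suffix of length k at read 5' end
    if (mismatches(read, 0, bc, L - k, k, max_mm) <= max_mm) return true;
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector cpp_match_reads(CharacterVector reads, CharacterVector barcodes,
                              CharacterVector barcodes_rc, double min_frac,
                              int max_mm, bool use_rc) {
  const int nb = barcodes.size();
  std::vector<std::string> bcs(nb), bcr(nb);
  for (int j = 0; j < nb; ++j) {
    bcs[j] = as<std::string>(barcodes[j]);
    if (use_rc) bcr[j] = as<std::string>(barcodes_rc[j]);
  }
  const int nr = reads.size();
  IntegerVector out(nr);
  for (int i = 0; i < nr; ++i) {
    std::string read = as<std::string>(reads[i]);
    bool invalid = false;
    for (size_t c = 0; c < read.size(); ++c) {
      if (!base_ok(read[c])) { invalid = true; break; }
    }
    if (invalid || read.empty()) { out[i] = -2; continue; }
    int hit = 0, nhit = 0;
    for (int j = 0; j < nb; ++j) {
      bool cand = is_candidate(read, bcs[j], min_frac, max_mm);
      if (!cand && use_rc) cand = is_candidate(read, bcr[j], min_frac, max_mm);
      if (cand) {
        ++nhit;
        hit = j + 1;
        if (nhit > 1) break;
      }
    }
    out[i] = (nhit == 0) ? 0 : (nhit > 1 ? -1 : hit);
  }
  return out;
}
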