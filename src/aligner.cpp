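#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ungapped all-placements Hamming scan of fixed-alphabet reads against one
// reference. Both orientations are searched: the caller supplies the
// reverse-complemented read set. 'N' matches nothing except 'N' itself
// (reads are expected to be ACGT; the rule only matters for degenerate
// references). Every placement with <= max_mismatch mismatches is reported.
// [[Rcpp::export]]
DataFrame cpp_align_hamming(CharacterVector reads, CharacterVector reads_rc,
                            std::string ref, int max_mismatch) {
  std::vector<int> out_read, out_off, out_orient, out_mm;
  const char* R = ref.c_str();
  const int n = (int) ref.size();
  const int n_reads = reads.size();
  for (int r = 0; r < n_reads; ++r) {
    for (int o = 0; o < 2; ++o) {
      SEXP sx = (o == 0) ? STRING_ELT(reads, r) : STRING_ELT(reads_rc, r);
      const char* s = CHAR(sx);
      const int L = (int) std::strlen(s);
      if (L == 0 || L > n) continue;
      const int last = n - L;
      for (int p = 0; p <= last; ++p) {
        int mm = 0;
        const char* Rp = R + p;
        for (int i = 0; i < L; ++i) {
          if (s[i] != Rp[i]) {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm <= max_mismatch) {
          out_read.push_back(r + 1);
          out_off.push_back(p);
          out_orient.push_back(o);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["offset"] = out_off,
                           _["orient"] = out_orient, _["mismatches"] = out_mm);
}
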