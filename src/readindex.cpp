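#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact-substring probe index over a read set and its reverse complements.
// Every probe-length window of every read (both orientations) is hashed by
// its 2-bit encoding; windows containing non-ACGT characters are skipped,
// which makes probes containing 'N' unmatchable by construction.

namespace {

struct ProbeIndex {
  int k;
  std::vector<std::string> fwd;
  std::vector<std::string> rc;
  // value packs (read << 17) | (offset << 1) | strand  (strand 1 = rc)
  std::unordered_map<uint64_t, std::vector<uint64_t> > map;
};

inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// Encode s[pos .. pos+k). Returns false when a non-ACGT char is present.
inline bool encode_kmer(const std::string& s, int pos, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t) b;
  }
  return true;
}

void index_string(ProbeIndex& ix, const std::string& s, uint64_t read,
                  int strand) {
  const int k = ix.k;
  const int n = (int) s.size();
  if (n < k) return;
  for (int p = 0; p + k <= n; ++p) {
    uint64_t code;
    if (!encode_kmer(s, p, k, code))
      continue;
    ix.map[code].push_back((read << 17) | ((uint64_t) p << 1) |
                           (uint64_t) strand);
  }
}

} // namespace

// [[Rcpp::export]]
SEXP cpp_probe_index_build(CharacterVector reads, CharacterVector reads_rc,
                           int probe_len) {
  ProbeIndex* ix = new ProbeIndex();
  ix->k = probe_len;
  const int n = reads.size();
  ix->fwd.reserve(n);
  ix->rc.reserve(n);
  for (int r = 0; r < n; ++r) {
    ix->fwd.push_back(as<std::string>(reads[r]));
    ix->rc.push_back(as<std::string>(reads_rc[r]));
    index_string(*ix, ix->fwd[r], (uint64_t) r, 0);
    index_string(*ix, ix->rc[r], (uint64_t) r, 1);
  }
  XPtr<ProbeIndex> xp(ix, true);
  return xp;
}

// [[Rcpp::export]]
DataFrame cpp_probe_index_query(SEXP xp_, std::string probe) {
  XPtr<ProbeIndex> xp(xp_);
  std::vector<int> read, offset, strand;
  uint64_t code;
  if ((int) probe.size() == xp->k && encode_kmer(probe, 0, xp->k, code)) {
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        xp->map.find(code);
    if (it != xp->map.end()) {
      for (size_t i = 0; i < it->second.size(); ++i) {
        uint64_t v = it->second[i];
        read.push_back((int) (v >> 17) + 1);
        offset.push_back((int) ((v >> 1) & 0xFFFF));
        strand.push_back((int) (v & 1));
      }
    }
  }
  return DataFrame::create(_["read"] = read, _["offset"] = offset,
                           _["strand"] = strand);
}

// Strict-majority consensus of the probe_len bases following every exact
// occurrence of `probe` in the indexed reads (either orientation). A
// position's call is the base covered by more than half of that position's
// total tally; ties, sub-majority pluralities, and zero coverage give 'N'.
// [[Rcpp::export]]
std::string cpp_find_next_probe(SEXP xp_, std::string probe) {
  XPtr<ProbeIndex> xp(xp_);
  const int k = xp->k;
  std::vector<int> counts(4 * k, 0);
  uint64_t code;
  if ((int) probe.size() == k && encode_kmer(probe, 0, k, code)) {
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
        xp->map.find(code);
    if (it != xp->map.end()) {
      for (size_t i = 0; i < it->second.size(); ++i) {
        uint64_t v = it->second[i];
        int r = (int) (v >> 17);
        int off = (int) ((v >> 1) & 0xFFFF);
        const std::string& s = (v & 1) ? xp->rc[r] : xp->fwd[r];
        const int n = (int) s.size();
        for (int p = 0; p < k; ++p) {
          int pos = off + k + p;
          if (pos >= n) break;
          int b = base2bits(s[pos]);
          if (b >= 0) counts[4 * p + b]++;
        }
      }
    }
  }
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string out(k, 'N');
  for (int p = 0; p < k; ++p) {
    int total = 0, best = 0, best_b = -1;
    for (int b = 0; b < 4; ++b) {
      int c = counts[4 * p + b];
      total += c;
      if (c > best) { best = c; best_b = b; }
    }
    if (total > 0 && best_b >= 0 && 2 * best > total)
      out[p] = BASES[best_b];
  }
  return out;
}
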