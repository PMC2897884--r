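#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Splice-aware semi-global aligner of a transcript-side sequence ("bes")
// against a genomic window, with asymmetric linear gap penalties:
//   * gap in the window (base inserted in bes):  gap_scaffold per base
//   * gap in the bes    (window base skipped):   gap_bes per base (an intron)
//   * window overhang before/after the bes:      free (semi-global)
// Match/mismatch/N scoring is positional; any column containing 'N' scores
// n_match. A hard structural constraint is enforced inside the DP: every
// maximal diagonal (aligned) run must span at least min_block bes bases.
// The run length is tracked as a capped counter state (1..min_block), so the
// optimum is global under the constraint rather than repaired afterwards.
//
// Tie-breaking is deterministic and lexicographic: (1) maximize score,
// (2) minimize the number of intron openings (maximal window-gap runs) --
// transcript-to-genome placement is frequently ambiguous at equal score and
// the variant with fewest introns is the canonical choice -- then (3) a
// fixed predecessor preference and the earliest window offset at the end.

namespace {

const int NEG = INT_MIN / 4;

inline int col_score(char a, char b, int match, int mismatch, int n_match) {
  if (a == 'N' || b == 'N') return n_match;
  return (a == b) ? match : mismatch;
}

struct Cand {
  int score;
  int introns;
};

// is (s1,n1) strictly better than (s2,n2)?
inline bool better(int s1, int n1, int s2, int n2) {
  return s1 > s2 || (s1 == s2 && n1 < n2);
}

} // namespace

// [[Rcpp::export]]
List cpp_spliced_align(std::string bes, std::string win, int match,
                       int mismatch, int n_match, int gap_scaffold,
                       int gap_bes, int min_block) {
  const int m = (int) bes.size();
  const int n = (int) win.size();
  const int K = min_block; // diagonal-run states 1..K
  if (m == 0)
    return List::create(_["score"] = 0, _["type"] = IntegerVector(0),
                        _["bi"] = IntegerVector(0), _["wj"] = IntegerVector(0));

  // rolling score and intron-count rows per state
  std::vector<std::vector<int> > prevD(K + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int> > curD(K + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int> > prevDn(K + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int> > curDn(K + 1, std::vector<int>(n + 1, 0));
  std::vector<int> prevI(n + 1, NEG), curI(n + 1, NEG);
  std::vector<int> prevIn(n + 1, 0), curIn(n + 1, 0);
  std::vector<int> prevG(n + 1, NEG), curG(n + 1, NEG);
  std::vector<int> prevGn(n + 1, 0), curGn(n + 1, 0);

  // traceback choices (full matrices)
  const size_t sz = (size_t)(m + 1) * (size_t)(n + 1);
  // D1: 0 start, 1 I, 2 G (K==1 adds 3 = D1) ; DK: 0 D(K-1), 1 DK ;
  // I: 0 DK, 1 I, 2 G, 3 start ; G: 0 DK, 1 I, 2 G
  std::vector<unsigned char> tbD1(sz, 0), tbDK(sz, 0), tbI(sz, 0), tbG(sz, 0);

  int best = NEG, best_n = 0, best_j = -1, best_state = -1; // 0 = DK, 1 = I

  for (int i = 1; i <= m; ++i) {
    const char bc = bes[i - 1];
    const size_t row = (size_t) i * (size_t)(n + 1);
    for (int k = 1; k <= K; ++k) curD[k][0] = NEG;
    { // insertion column at j = 0
      int v = NEG, nn = 0; unsigned char ch = 0;
      if (better(prevI[0], prevIn[0], v, nn)) {
        v = prevI[0]; nn = prevIn[0]; ch = 1;
      }
      if (i == 1 && better(0, 0, v, nn)) { v = 0; nn = 0; ch = 3; }
      curI[0] = (v == NEG) ? NEG : v + gap_scaffold;
      curIn[0] = nn;
      tbI[row + 0] = ch;
    }
    curG[0] = NEG; curGn[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const int s = col_score(bc, win[j - 1], match, mismatch, n_match);
      { // D1: start a new diagonal run
        int v = NEG, nn = 0; unsigned char ch = 0;
        if (i == 1) { v = 0; nn = 0; ch = 0; } // free leading window skip
        if (better(prevI[j - 1], prevIn[j - 1], v, nn)) {
          v = prevI[j - 1]; nn = prevIn[j - 1]; ch = 1;
        }
        if (better(prevG[j - 1], prevGn[j - 1], v, nn)) {
          v = prevG[j - 1]; nn = prevGn[j - 1]; ch = 2;
        }
        if (K == 1 && better(prevD[1][j - 1], prevDn[1][j - 1], v, nn)) {
          v = prevD[1][j - 1]; nn = prevDn[1][j - 1]; ch = 3;
        }
        curD[1][j] = (v == NEG) ? NEG : v + s;
        curDn[1][j] = nn;
        tbD1[row + j] = ch;
      }
      for (int k = 2; k < K; ++k) { // forced continuation
        curD[k][j] = (prevD[k - 1][j - 1] == NEG) ? NEG
                                                  : prevD[k - 1][j - 1] + s;
        curDn[k][j] = prevDn[k - 1][j - 1];
      }
      if (K >= 2) { // DK: run length >= K
        int v = NEG, nn = 0; unsigned char ch = 0;
        if (prevD[K - 1][j - 1] != NEG &&
            better(prevD[K - 1][j - 1], prevDn[K - 1][j - 1], v, nn)) {
          v = prevD[K - 1][j - 1]; nn = prevDn[K - 1][j - 1]; ch = 0;
        }
        if (better(prevD[K][j - 1], prevDn[K][j - 1], v, nn)) {
          v = prevD[K][j - 1]; nn = prevDn[K][j - 1]; ch = 1;
        }
        curD[K][j] = (v == NEG) ? NEG : v + s;
        curDn[K][j] = nn;
        tbDK[row + j] = ch;
      }
      { // I: bes base aligned to nothing
        int v = NEG, nn = 0; unsigned char ch = 0;
        if (prevD[K][j] != NEG && better(prevD[K][j], prevDn[K][j], v, nn)) {
          v = prevD[K][j]; nn = prevDn[K][j]; ch = 0;
        }
        if (better(prevI[j], prevIn[j], v, nn)) {
          v = prevI[j]; nn = prevIn[j]; ch = 1;
        }
        if (better(prevG[j], prevGn[j], v, nn)) {
          v = prevG[j]; nn = prevGn[j]; ch = 2;
        }
        if (i == 1 && better(0, 0, v, nn)) { v = 0; nn = 0; ch = 3; }
        curI[j] = (v == NEG) ? NEG : v + gap_scaffold;
        curIn[j] = nn;
        tbI[row + j] = ch;
      }
      { // G: window base skipped (intron); entering from D/I opens one
        int v = NEG, nn = 0; unsigned char ch = 0;
        if (curD[K][j - 1] != NEG &&
            better(curD[K][j - 1], curDn[K][j - 1] + 1, v, nn)) {
          v = curD[K][j - 1]; nn = curDn[K][j - 1] + 1; ch = 0;
        }
        if (curI[j - 1] != NEG &&
            better(curI[j - 1], curIn[j - 1] + 1, v, nn)) {
          v = curI[j - 1]; nn = curIn[j - 1] + 1; ch = 1;
        }
        if (curG[j - 1] != NEG &&
            better(curG[j - 1], curGn[j - 1], v, nn)) {
          v = curG[j - 1]; nn = curGn[j - 1]; ch = 2;
        }
        curG[j] = (v == NEG) ? NEG : v + gap_bes;
        curGn[j] = nn;
        tbG[row + j] = ch;
      }
    }
    if (i == m) {
      for (int j = 0; j <= n; ++j) {
        if (curD[K][j] != NEG &&
            better(curD[K][j], curDn[K][j], best, best_n)) {
          best = curD[K][j]; best_n = curDn[K][j]; best_j = j;
          best_state = 0;
        }
        if (curI[j] != NEG && better(curI[j], curIn[j], best, best_n)) {
          best = curI[j]; best_n = curIn[j]; best_j = j; best_state = 1;
        }
      }
    }
    prevD.swap(curD); prevDn.swap(curDn);
    prevI.swap(curI); prevIn.swap(curIn);
    prevG.swap(curG); prevGn.swap(curGn);
  }

  if (best_j < 0 || best <= NEG / 2)
    return List::create(_["score"] = NA_INTEGER, _["type"] = IntegerVector(0),
                        _["bi"] = IntegerVector(0), _["wj"] = IntegerVector(0));

  // traceback: states 1..K diagonal, 100 = I, 200 = G, -1 = done
  std::vector<int> ty, bi, wj; // type: 0 diag, 1 insertion, 2 deletion
  int i = m, j = best_j;
  int st = (best_state == 0) ? K : 100;
  while (st != -1) {
    const size_t row = (size_t) i * (size_t)(n + 1);
    if (st >= 1 && st <= K) {
      ty.push_back(0); bi.push_back(i - 1); wj.push_back(j - 1);
      if (st == 1) {
        unsigned char ch = tbD1[row + j];
        --i; --j;
        if (K == 1) {
          st = (ch == 0) ? -1 : (ch == 1 ? 100 : (ch == 2 ? 200 : 1));
        } else {
          st = (ch == 0) ? -1 : (ch == 1 ? 100 : 200);
        }
      } else if (st == K) {
        unsigned char ch = tbDK[row + j];
        --i; --j;
        st = (ch == 0) ? (K - 1) : K;
      } else {
        --i; --j;
        st = st - 1;
      }
    } else if (st == 100) {
      ty.push_back(1); bi.push_back(i - 1); wj.push_back(-1);
      unsigned char ch = tbI[row + j];
      --i;
      st = (ch == 0) ? K : (ch == 1 ? 100 : (ch == 2 ? 200 : -1));
    } else { // G
      ty.push_back(2); bi.push_back(-1); wj.push_back(j - 1);
      unsigned char ch = tbG[row + j];
      --j;
      st = (ch == 0) ? K : (ch == 1 ? 100 : 200);
    }
  }
  std::reverse(ty.begin(), ty.end());
  std::reverse(bi.begin(), bi.end());
  std::reverse(wj.begin(), wj.end());
  return List::create(_["score"] = best, _["type"] = wrap(ty),
                      _["bi"] = wrap(bi), _["wj"] = wrap(wj));
}
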