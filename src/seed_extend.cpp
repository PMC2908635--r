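// Word-seeded ungapped extension engine.
//
// Probe and subject sequences arrive as integer codes (A=0, C=1, G=2, T=3;
// subject separator sentinels use 9, which can never match a probe base).
// Seeds are exact wordSize-mers; extension is ungapped under an X-drop
// rule and ends at the running-score maxima.  Hits shorter than minWindow
// or whose best minWindow-nt sub-window falls below minWindowIdentity are
// discarded.  One extension is performed per (diagonal, uncovered seed).

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".seedExtendCore")]]
DataFrame seed_extend_core(IntegerVector p, IntegerVector S, IntegerVector W,
                           int wordSize, int matchReward, int mismatchPenalty,
                           int minWindow, double minWindowIdentity,
                           int xDrop) {
  const int n = p.size();
  const int nw = W.size();
  const int nWords = 1 << (2 * wordSize);

  // probe word table: head/next chains over probe positions
  std::vector<int> head(nWords, -1), nxt(std::max(n - wordSize + 1, 0), -1);
  bool anyWord = false;
  {
    int code = 0, run = 0;
    for (int q = 0; q < n; ++q) {
      code = ((code << 2) | (p[q] & 3)) & (nWords - 1);
      run++;
      if (run >= wordSize) {
        int pos = q - wordSize + 1;       // 0-based start of the word
        nxt[pos] = head[code];
        head[code] = pos;
        anyWord = true;
      }
    }
  }

  std::vector<int> qsv, qev, ssv, matchv, lenv;
  if (anyWord) {
    std::map<long long, std::pair<int, int> > covered;  // diagonal -> q range
    const int minMatches = (int)std::ceil(minWindowIdentity / 100.0 *
                                          minWindow);
    for (int s = 0; s < nw; ++s) {
      int wv = W[s];
      if (wv < 0) continue;
      for (int i = head[wv]; i != -1; i = nxt[i]) {
        long long d = (long long)s - i;
        std::map<long long, std::pair<int, int> >::iterator it =
          covered.find(d);
        if (it != covered.end() && i >= it->second.first &&
            i + wordSize - 1 <= it->second.second)
          continue;
        int qs = i, qe = i + wordSize - 1;           // 0-based, inclusive
        // right extension: full X-drop extent, trimmed to the last match
        {
          int run = 0, best = 0, lastMatch = qe;
          for (int q = qe + 1; q < n; ++q) {
            long long j = q + d;
            bool m = (j >= 0 && j < S.size() && S[j] == p[q]);
            run += m ? matchReward : -mismatchPenalty;
            if (m) lastMatch = q;
            if (run > best) best = run;
            if (best - run > xDrop) break;
          }
          qe = lastMatch;
        }
        // left extension
        {
          int run = 0, best = 0, lastMatch = qs;
          for (int q = qs - 1; q >= 0; --q) {
            long long j = q + d;
            bool m = (j >= 0 && j < S.size() && S[j] == p[q]);
            run += m ? matchReward : -mismatchPenalty;
            if (m) lastMatch = q;
            if (run > best) best = run;
            if (best - run > xDrop) break;
          }
          qs = lastMatch;
        }
        // record coverage whether or not the hit qualifies
        if (it != covered.end()) {
          if (qs < it->second.first) it->second.first = qs;
          if (qe > it->second.second) it->second.second = qe;
        } else {
          covered[d] = std::make_pair(qs, qe);
        }
        int len = qe - qs + 1;
        if (len < minWindow) continue;
        // matches and best sliding window
        int total = 0, win = 0, bestWin = 0;
        std::vector<int> mv(len);
        for (int k = 0; k < len; ++k) {
          long long j = qs + k + d;
          int m = (j >= 0 && j < S.size() && S[j] == p[qs + k]) ? 1 : 0;
          mv[k] = m;
          total += m;
          win += m;
          if (k >= minWindow) win -= mv[k - minWindow];
          if (k >= minWindow - 1 && win > bestWin) bestWin = win;
        }
        if (bestWin < minMatches) continue;
        qsv.push_back(qs + 1);
        qev.push_back(qe + 1);
        ssv.push_back((int)(qs + d) + 1);
        matchv.push_back(total);
        lenv.push_back(len);
      }
    }
  }
  return DataFrame::create(_["q_start"] = wrap(qsv), _["q_end"] = wrap(qev),
                           _["s_abs"] = wrap(ssv),
                           _["matches"] = wrap(matchv),
                           _["length"] = wrap(lenv));
}
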