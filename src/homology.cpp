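#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped diagonal scan of a probe against one genome strand.
//
// Bases are integer-encoded (A=1, C=2, G=3, T=4, anything else 0); code 0
// never matches, including against itself, so N runs cannot create hits.
//
// Three rule families are evaluated on every diagonal (every ungapped
// alignment offset of the probe against the genome):
//   * exact runs strictly longer than `min_run` matching bases;
//   * for each (win_len[k], win_min[k]) pair, sliding windows of length
//     win_len[k] containing >= win_min[k] matches (thresholds are
//     precomputed in R so that "more than X% similarity" stays strict).
// Qualifying windows on a diagonal are unioned before emission, so the
// returned intervals are maximal per diagonal per rule.
//
// Returns a matrix with one row per emitted interval:
//   start, end (1-based genome coordinates), rule (0 = exact run,
//   k >= 1 = window rule k), matches, span.
// [[Rcpp::export]]
IntegerMatrix homology_scan_strand(IntegerVector probe, IntegerVector genome,
                                   int min_run, IntegerVector win_len,
                                   IntegerVector win_min) {
  const int P = probe.size();
  const int G = genome.size();
  const int n_rules = win_len.size();

  int min_need = min_run + 1;
  for (int k = 0; k < n_rules; ++k)
    if (win_len[k] < min_need) min_need = win_len[k];

  std::vector<int> out;  // flat rows: start, end, rule, matches, span
  std::vector<unsigned char> m(P);

  for (int d = -(P - 1); d <= G - 1; ++d) {
    const int i0 = std::max(0, -d);      // probe index range [i0, i1)
    const int i1 = std::min(P, G - d);
    const int L = i1 - i0;
    if (L < min_need) continue;

    for (int i = i0; i < i1; ++i) {
      const int pb = probe[i];
      m[i - i0] = (pb != 0 && pb == genome[d + i]) ? 1 : 0;
    }

    // exact runs strictly longer than min_run
    int run = 0;
    for (int j = 0; j <= L; ++j) {
      if (j < L && m[j]) {
        ++run;
      } else {
        if (run > min_run) {
          const int gs = d + i0 + j - run;  // 0-based genome start
          out.push_back(gs + 1);
          out.push_back(gs + run);
          out.push_back(0);
          out.push_back(run);
          out.push_back(run);
        }
        run = 0;
      }
    }

    // windowed similarity rules
    for (int k = 0; k < n_rules; ++k) {
      const int W = win_len[k];
      if (L < W) continue;
      const int need = win_min[k];
      int cnt = 0;
      for (int j = 0; j < W; ++j) cnt += m[j];
      int emit_s = -1, emit_e = -1, best = 0;
      for (int j = 0; j + W <= L; ++j) {
        if (j > 0) cnt += m[j + W - 1] - m[j - 1];
        if (cnt >= need) {
          const int gs = d + i0 + j;  // 0-based window start
          if (emit_s < 0) {
            emit_s = gs; emit_e = gs + W - 1; best = cnt;
          } else if (gs <= emit_e + 1) {
            emit_e = gs + W - 1;
            if (cnt > best) best = cnt;
          } else {
            out.push_back(emit_s + 1); out.push_back(emit_e + 1);
            out.push_back(k + 1); out.push_back(best); out.push_back(W);
            emit_s = gs; emit_e = gs + W - 1; best = cnt;
          }
        }
      }
      if (emit_s >= 0) {
        out.push_back(emit_s + 1); out.push_back(emit_e + 1);
        out.push_back(k + 1); out.push_back(best); out.push_back(W);
      }
    }
  }

  const int n = out.size() / 5;
  IntegerMatrix res(n, 5);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < 5; ++c) res(r, c) = out[5 * r + c];
  colnames(res) = CharacterVector::create("start", "end", "rule",
                                          "matches", "span");
  return res;
}
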