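// Affine-gap local alignment (Smith-Waterman with Gotoh's three-state
// recurrence) of a bisulfite read against a converted amplicon reference.
// The reference may contain the wildcards Y (matches C or T) and R (matches
// A or G), so methylation state never penalises the alignment. Gap cost for
// a run of length L is gap_open + (L - 1) * gap_extend.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pair_score(char r, char t, double match, double mismatch) {
  if (t == 'Y') return (r == 'C' || r == 'T') ? match : mismatch;
  if (t == 'R') return (r == 'A' || r == 'G') ? match : mismatch;
  if (r == 'N' || t == 'N') return mismatch;
  return (r == t) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_gotoh")]]
List sw_gotoh(std::string read, std::string ref,
              double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = read.size(), m = ref.size();
  const double NEG = -1e18;
  // H: best score ending at (i, j); E: ending with a gap in the read
  // (consuming reference); F: ending with a gap in the reference
  // (consuming read). (n+1) x (m+1), row-major.
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[at(i, j - 1)] + gap_open,
                          E[at(i, j - 1)] + gap_extend);
      double f = std::max(H[at(i - 1, j)] + gap_open,
                          F[at(i - 1, j)] + gap_extend);
      double d = H[at(i - 1, j - 1)] +
        pair_score(read[i - 1], ref[j - 1], match, mismatch);
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }  // first maximal cell wins
    }
  }

  // traceback; tie-break: diagonal, then up (gap in reference, consumes
  // read), then left (gap in read); inside a gap state, prefer closing the
  // gap (returning to H) on ties.
  std::vector<int> rpos, tpos;  // 1-based; NA encoded later as 0
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      double h = H[at(i, j)];
      if (h <= 0.0) break;
      double d = H[at(i - 1, j - 1)] +
        pair_score(read[i - 1], ref[j - 1], match, mismatch);
      if (h == d) {
        rpos.push_back(i); tpos.push_back(j);
        --i; --j;
      } else if (h == F[at(i, j)]) {
        state = 'F';
      } else if (h == E[at(i, j)]) {
        state = 'E';
      } else {
        break;  // h == 0
      }
    } else if (state == 'F') {
      rpos.push_back(i); tpos.push_back(0);
      double f = F[at(i, j)];
      if (f == H[at(i - 1, j)] + gap_open) state = 'H';
      --i;
    } else {  // E
      rpos.push_back(0); tpos.push_back(j);
      double e = E[at(i, j)];
      if (e == H[at(i, j - 1)] + gap_open) state = 'H';
      --j;
    }
  }

  const int K = rpos.size();
  IntegerVector read_idx(K), ref_idx(K);
  int rs = 0, re = 0, ts = 0, te = 0;
  for (int k = 0; k < K; ++k) {
    int rk = rpos[K - 1 - k], tk = tpos[K - 1 - k];
    read_idx[k] = rk == 0 ? NA_INTEGER : rk;
    ref_idx[k] = tk == 0 ? NA_INTEGER : tk;
    if (rk > 0) { if (rs == 0) rs = rk; re = rk; }
    if (tk > 0) { if (ts == 0) ts = tk; te = tk; }
  }

  return List::create(_["score"] = best,
                      _["read_start"] = rs, _["read_end"] = re,
                      _["ref_start"] = ts, _["ref_end"] = te,
                      _["read_idx"] = read_idx, _["ref_idx"] = ref_idx);
}
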