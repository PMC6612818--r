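#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman-Gotoh) with a fully
// deterministic traceback. A gap of length g costs gap_open + g*gap_extend.
// Tie-breaks, mirrored exactly by the R test oracle:
//   * cell recurrence and traceback prefer diagonal (M) > up (I, consumes
//     query) > left (D, consumes target) > stop;
//   * within a gap state, ties prefer opening (returning to the main state)
//     over extending, i.e. shorter gaps;
//   * the traceback origin is the maximal cell with smallest query index,
//     then smallest target index.
// CIGAR uses M/I/D with S for unaligned query flanks; I consumes query,
// D consumes target (the reference in realignment use).

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("sw_align_cpp(): empty query or target");
  const int NEG = INT_MIN / 4;

  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG);  // ends in D (gap in query / consumes target)
  std::vector<int> F((n + 1) * (m + 1), NEG);  // ends in I (consumes query)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int e = std::max(H[at(i, j - 1)] + gap_open + gap_extend,
                             E[at(i, j - 1)] + gap_extend);
      const int f = std::max(H[at(i - 1, j)] + gap_open + gap_extend,
                             F[at(i - 1, j)] + gap_extend);
      const int s = (query[i - 1] == target[j - 1]) ? match : mismatch;
      const int d = H[at(i - 1, j - 1)] + s;
      int h = d;                 // diagonal preferred
      if (f > h) h = f;          // then up (I)
      if (e > h) h = e;          // then left (D)
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER, _["target_start"] = NA_INTEGER,
                        _["target_end"] = NA_INTEGER, _["cigar"] = NA_STRING);
  }

  // traceback
  std::string ops;  // reversed
  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    if (state == 'H') {
      const int h = H[at(i, j)];
      if (h == 0) break;
      const int s = (query[i - 1] == target[j - 1]) ? match : mismatch;
      if (h == H[at(i - 1, j - 1)] + s) { ops.push_back('M'); --i; --j; }
      else if (h == F[at(i, j)]) state = 'F';
      else state = 'E';
    } else if (state == 'F') {
      ops.push_back('I');
      const bool open = F[at(i, j)] == H[at(i - 1, j)] + gap_open + gap_extend;
      --i;
      if (open) state = 'H';  // prefer closing the gap on ties
    } else {  // E
      ops.push_back('D');
      const bool open = E[at(i, j)] == H[at(i, j - 1)] + gap_open + gap_extend;
      --j;
      if (open) state = 'H';
    }
  }
  const int qs = i + 1, ts = j + 1;  // 1-based starts of the aligned region

  // compress reversed ops into CIGAR, adding soft clips for query flanks
  std::string cig;
  auto app = [&cig](int len, char op) {
    if (len > 0) { cig += std::to_string(len); cig.push_back(op); }
  };
  app(qs - 1, 'S');
  int run = 0; char cur = 0;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    if (ops[k] == cur) ++run;
    else { app(run, cur ? cur : 'M'), run = 1, cur = ops[k]; }
  }
  app(run, cur);
  app(n - bi, 'S');

  return List::create(_["score"] = best, _["query_start"] = qs,
                      _["query_end"] = bi, _["target_start"] = ts,
                      _["target_end"] = bj, _["cigar"] = cig);
}
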