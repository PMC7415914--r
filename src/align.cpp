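#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman of a query against a reference, with full
// traceback. Gap of length L costs gap_open + L * gap_extend (BWA-MEM
// convention). Returns the single best-scoring local alignment; unaligned
// query ends are reported as soft-clips in the CIGAR.
//
// Three-state DP: H (match/mismatch), E (gap in query = deletion from the
// reference's point of view, ref-consuming), F (gap in reference =
// insertion, query-consuming). Local: H >= 0 everywhere.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string ref,
              int match = 1, int mismatch = 4,
              int gap_open = 6, int gap_extend = 1) {
  const int m = (int)query.size(), n = (int)ref.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0);
  const int NEG = -1000000000;

  // DP matrices stored fully for traceback: (m+1) x (n+1)
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // E: deletion (ref-consuming, horizontal over ref j)
      int e = std::max(H[idx(i, j - 1)] - gap_open - gap_extend,
                       E[idx(i, j - 1)] - gap_extend);
      // F: insertion (query-consuming, vertical over query i)
      int f = std::max(H[idx(i - 1, j)] - gap_open - gap_extend,
                       F[idx(i - 1, j)] - gap_extend);
      int s = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
      int h = H[idx(i - 1, j - 1)] + s;
      h = std::max(h, std::max(e, f));
      if (h < 0) h = 0;
      H[idx(i, j)] = h;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);

  // Traceback from (bi, bj) in state H until H == 0.
  // ops: 'M' (diag), 'D' (ref-only), 'I' (query-only)
  std::string ops;
  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    if (state == 'H') {
      int h = H[idx(i, j)];
      if (h == 0) break;
      int s = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
      if (i > 0 && j > 0 && h == H[idx(i - 1, j - 1)] + s) {
        ops.push_back('M'); --i; --j;
      } else if (h == E[idx(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ops.push_back('D');
      int e = E[idx(i, j)];
      if (e == E[idx(i, j - 1)] - gap_extend) { --j; }
      else { --j; state = 'H'; }
    } else { // F
      ops.push_back('I');
      int f = F[idx(i, j)];
      if (f == F[idx(i - 1, j)] - gap_extend) { --i; }
      else { --i; state = 'H'; }
    }
  }
  std::reverse(ops.begin(), ops.end());

  const int qstart = i, rstart = j;          // 0-based starts
  // run-length encode with soft clips
  std::string cigar;
  auto app = [&cigar](int len, char op) {
    if (len > 0) cigar += std::to_string(len) + op;
  };
  app(qstart, 'S');
  int run = 0; char cur = 0;
  for (char c : ops) {
    if (c == cur) { ++run; }
    else { app(run, cur ? cur : 'M'); cur = c; run = 1; }
  }
  app(run, cur);
  app(m - bi, 'S');

  return List::create(
    _["score"] = best,
    _["ref_start"] = rstart,
    _["ref_end"] = bj,
    _["query_start"] = qstart,
    _["query_end"] = bi,
    _["cigar"] = cigar);
}
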