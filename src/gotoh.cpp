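#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Affine-gap global alignment (Gotoh) over a precomputed column-score
// matrix S (nrow = length of profile a, ncol = length of profile b).
// Gap of length k costs gap_open + (k - 1) * gap_extend (both <= 0).
// Tie-break, fixed for reproducibility: aligned pair > gap-in-a > gap-in-b.
//
// Returns 1-based index vectors into a and b (0 = gap) plus the optimal score.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  // states: 0 = M (pair), 1 = GA (gap in a, consumes b), 2 = GB (gap in b)
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), GA((n + 1) * W, NEG),
      GB((n + 1) * W, NEG);
  std::vector<signed char> tM((n + 1) * W, -1), tGA((n + 1) * W, -1),
      tGB((n + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    GA[j] = gap_open + (j - 1) * gap_extend;
    tGA[j] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    GB[i * W] = gap_open + (i - 1) * gap_extend;
    tGB[i * W] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M from diagonal, preferring M > GA > GB on ties
      double best = M[d];
      signed char who = 0;
      if (GA[d] > best) { best = GA[d]; who = 1; }
      if (GB[d] > best) { best = GB[d]; who = 2; }
      M[c] = best + S(i - 1, j - 1);
      tM[c] = who;
      // GA: gap character in a, consumes b[j]
      best = M[l] + gap_open; who = 0;
      if (GA[l] + gap_extend > best) { best = GA[l] + gap_extend; who = 1; }
      if (GB[l] + gap_open > best) { best = GB[l] + gap_open; who = 2; }
      GA[c] = best; tGA[c] = who;
      // GB: gap character in b, consumes a[i]
      best = M[u] + gap_open; who = 0;
      if (GA[u] + gap_open > best) { best = GA[u] + gap_open; who = 1; }
      if (GB[u] + gap_extend > best) { best = GB[u] + gap_extend; who = 2; }
      GB[c] = best; tGB[c] = who;
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (GA[end] > score) { score = GA[end]; state = 1; }
  if (GB[end] > score) { score = GB[end]; state = 2; }

  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      ai.push_back(0); bi.push_back(j);
      state = tGA[c]; --j;
    } else {
      ai.push_back(i); bi.push_back(0);
      state = tGB[c]; --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = score);
}
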