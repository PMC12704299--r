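#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (three-state Gotoh DP) of a read against a
// reference. An L-base gap costs gap_open + L * gap_extend; independent gap
// runs each pay their own open, and a deletion run may directly follow an
// insertion run (all inter-state transitions allowed). Traceback is
// deterministic with preference diagonal > vertical (read base against a
// gap, i.e. insertion) > horizontal (deletion).
//
// States: 0 = M (diagonal), 1 = I (consume read, gap in reference),
// 2 = D (consume reference, gap in read).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string read, std::string ref,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int m = read.size(), n = ref.size();
  if (m == 0 || n == 0) stop("read and reference must be non-empty");
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), I((m + 1) * W, NEG_INF),
      D((m + 1) * W, NEG_INF);
  // ptr: for each state matrix, which predecessor state the optimum came
  // from (0/1/2), or -1 at origin.
  std::vector<signed char> pM((m + 1) * W, -1), pI((m + 1) * W, -1),
      pD((m + 1) * W, -1);
  M[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    D[j] = gap_open + j * gap_extend;
    pD[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    I[i * W] = gap_open + i * gap_extend;
    pI[i * W] = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, dg = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: diagonal step; prefer predecessor M > I > D at ties
      double s = (rb == ref[j - 1] && rb != 'N') ? match : mismatch;
      double best = M[dg]; signed char arg = 0;
      if (I[dg] > best) { best = I[dg]; arg = 1; }
      if (D[dg] > best) { best = D[dg]; arg = 2; }
      if (best > NEG_INF) { M[c] = best + s; pM[c] = arg; }
      // I: consume read base, gap in reference
      double open_m = M[up] + gap_open + gap_extend;
      double ext = I[up] + gap_extend;
      double open_d = D[up] + gap_open + gap_extend;
      best = open_m; arg = 0;
      if (ext > best) { best = ext; arg = 1; }
      if (open_d > best) { best = open_d; arg = 2; }
      if (best > NEG_INF) { I[c] = best; pI[c] = arg; }
      // D: consume reference base, gap in read
      open_m = M[lf] + gap_open + gap_extend;
      double open_i = I[lf] + gap_open + gap_extend;
      ext = D[lf] + gap_extend;
      best = open_m; arg = 0;
      if (open_i > best) { best = open_i; arg = 1; }
      if (ext > best) { best = ext; arg = 2; }
      if (best > NEG_INF) { D[c] = best; pD[c] = arg; }
    }
  }
  // Final state: prefer M > I > D at ties
  const int end = m * W + n;
  double score = M[end]; int state = 0;
  if (I[end] > score) { score = I[end]; state = 1; }
  if (D[end] > score) { score = D[end]; state = 2; }
  // Traceback
  std::string ra, qa;  // reference row, read row (reversed)
  int i = m, j = n;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      prev = pM[i * W + j];
      ra.push_back(ref[j - 1]); qa.push_back(read[i - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = pI[i * W + j];
      ra.push_back('-'); qa.push_back(read[i - 1]);
      --i;
    } else {
      prev = pD[i * W + j];
      ra.push_back(ref[j - 1]); qa.push_back('-');
      --j;
    }
    state = (prev < 0) ? 0 : prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["score"] = score, _["ref_aln"] = ra,
                      _["read_aln"] = qa);
}
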