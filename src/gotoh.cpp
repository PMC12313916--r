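#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap semi-global alignment (Gotoh): the read is aligned end to
// end, leading/trailing unaligned subject is free. A gap of length k
// costs open + k * extend (penalties passed as negative numbers). Bases
// match only when equal and unambiguous (N never matches, conservatively).
// Traceback is deterministic: among equal-scoring moves the diagonal is
// preferred, then a gap in the subject, then a gap in the read; the
// alignment end is the leftmost subject column achieving the best score.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string read, std::string subject, double match,
                 double mismatch, double gap_open, double gap_extend,
                 bool traceback) {
  const int n = (int)read.size(), m = (int)subject.size();
  if (n == 0 || m == 0) stop("empty read or subject");
  const double oe = gap_open + gap_extend, e = gap_extend;

  std::vector<double> H(m + 1), E(m + 1), Hp(m + 1), Ep(m + 1), F(m + 1);
  // trace codes per cell: choice of H (0 diag, 1 E, 2 F), plus gap-origin
  // bits for E and F
  std::vector<unsigned char> TH, TE, TF;
  if (traceback) {
    TH.assign((size_t)n * m, 0);
    TE.assign((size_t)n * m, 0);
    TF.assign((size_t)n * m, 0);
  }

  for (int j = 0; j <= m; ++j) { Hp[j] = 0.0; Ep[j] = NEG; }
  double best = NEG; int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    H[0] = gap_open + e * i;   // whole read prefix as a gap in the subject
    E[0] = H[0];
    F[0] = NEG;
    const char rc = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char sc = subject[j - 1];
      const double s = (rc == sc && rc != 'N') ? match : mismatch;

      double e_open = Hp[j] + oe, e_ext = Ep[j] + e;
      E[j] = (e_open >= e_ext) ? e_open : e_ext;
      unsigned char te = (e_open >= e_ext) ? 0 : 1;

      double f_open = H[j - 1] + oe, f_ext = F[j - 1] + e;
      F[j] = (f_open >= f_ext) ? f_open : f_ext;
      unsigned char tf = (f_open >= f_ext) ? 0 : 1;

      double diag = Hp[j - 1] + s;
      double h = diag; unsigned char th = 0;
      if (E[j] > h) { h = E[j]; th = 1; }
      if (F[j] > h) { h = F[j]; th = 2; }
      H[j] = h;
      if (traceback) {
        size_t k = (size_t)(i - 1) * m + (j - 1);
        TH[k] = th; TE[k] = te; TF[k] = tf;
      }
    }
    std::swap(H, Hp); std::swap(E, Ep);
    if (i == n) {
      for (int j = 0; j <= m; ++j)     // leftmost best end column
        if (Hp[j] > best) { best = Hp[j]; best_i = n; best_j = j; }
    }
  }

  if (!traceback)
    return List::create(_["score"] = best);

  // walk back from (n, best_j) to row 0
  std::string ap, as;
  int i = best_i, j = best_j;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  int end_j = best_j, start_j = best_j;
  while (i > 0) {
    if (j == 0) {  // leading read insertion against nothing
      ap.push_back(read[i - 1]); as.push_back('-'); --i; continue;
    }
    size_t k = (size_t)(i - 1) * m + (j - 1);
    if (state == 0) state = TH[k];
    if (state == 0) {
      ap.push_back(read[i - 1]); as.push_back(subject[j - 1]);
      --i; --j;
    } else if (state == 1) {           // gap in subject, consume read base
      ap.push_back(read[i - 1]); as.push_back('-');
      state = (TE[k] == 0) ? 0 : 1;
      --i;
    } else {                           // gap in read, consume subject base
      ap.push_back('-'); as.push_back(subject[j - 1]);
      state = (TF[k] == 0) ? 0 : 2;
      --j;
    }
  }
  start_j = j;
  std::reverse(ap.begin(), ap.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = best, _["offset"] = start_j,
                      _["end"] = end_j, _["aln_pattern"] = ap,
                      _["aln_subject"] = as);
}
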