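#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh recursion).
// A gap of length L costs gap_open + L * gap_ext (NCBI convention, so the
// first gapped residue costs gap_open + gap_ext). Traceback is
// deterministic: at each match-state cell ties are resolved preferring the
// diagonal, then the vertical (gap in b), then the horizontal (gap in a)
// predecessor; the best cell is the first maximum in row-major order.
//
// Returns score plus alignment-column statistics needed for identity and
// coverage filters: matches, alignment length (columns incl. gap columns)
// and 1-based inclusive spans on both sequences (0s if the best score is 0).
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (!s.empty()) lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%c' absent from substitution matrix", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%c' absent from substitution matrix", b[j]);
  }
  const int ns = submat.nrow();
  std::vector<double> sm((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) sm[(size_t)i * ns + j] = submat(i, j);
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> H((size_t)(n + 1) * W, 0.0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // pointers: H: 0 stop, 1 diag, 2 up (F), 3 left (E); E/F: 1 open-from-H,
  // 2 extend
  std::vector<unsigned char> pH((size_t)(n + 1) * W, 0),
      pE((size_t)(n + 1) * W, 0), pF((size_t)(n + 1) * W, 0);
  double best = 0.0;
  int bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j;
      // E: gap in a (move left, consume b[j])
      double e_open = H[c - 1] - gap_open - gap_ext;
      double e_ext = E[c - 1] - gap_ext;
      if (e_open >= e_ext) { E[c] = e_open; pE[c] = 1; }
      else { E[c] = e_ext; pE[c] = 2; }
      // F: gap in b (move up, consume a[i])
      double f_open = H[c - W] - gap_open - gap_ext;
      double f_ext = F[c - W] - gap_ext;
      if (f_open >= f_ext) { F[c] = f_open; pF[c] = 1; }
      else { F[c] = f_ext; pF[c] = 2; }
      double diag = H[c - W - 1] + sm[(size_t)ai[i - 1] * ns + bi[j - 1]];
      double h = 0.0;
      unsigned char p = 0;
      if (diag >= h) { h = diag; p = 1; }
      if (F[c] > h) { h = F[c]; p = 2; }
      if (E[c] > h) { h = E[c]; p = 3; }
      if (h <= 0.0) { h = 0.0; p = 0; }
      H[c] = h;
      pH[c] = p;
      if (h > best) { best = h; bi_ = i; bj_ = j; }
    }
  }
  int matches = 0, columns = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  if (best > 0.0) {
    a_end = bi_; b_end = bj_;
    int i = bi_, j = bj_, state = 0;  // 0 = H, 1 = E, 2 = F
    while (true) {
      const size_t c = (size_t)i * W + j;
      if (state == 0) {
        unsigned char p = pH[c];
        if (p == 0) break;
        if (p == 1) {
          ++columns;
          if (a[i - 1] == b[j - 1]) ++matches;
          --i; --j;
        } else if (p == 2) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 2) {  // F: consume a[i], gap column
        ++columns;
        unsigned char p = pF[c];
        --i;
        state = (p == 1) ? 0 : 2;
      } else {  // E: consume b[j], gap column
        ++columns;
        unsigned char p = pE[c];
        --j;
        state = (p == 1) ? 0 : 1;
      }
    }
    a_start = i + 1;
    b_start = j + 1;
  }
  return List::create(_["score"] = best, _["aln_length"] = columns,
                      _["matches"] = matches, _["a_start"] = a_start,
                      _["a_end"] = a_end, _["b_start"] = b_start,
                      _["b_end"] = b_end);
}
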