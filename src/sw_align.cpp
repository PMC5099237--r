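#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L scores gap_open + L * gap_extend (both <= 0).
// Returns best score and 1-based alignment coordinates on both sequences.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string const &q, std::string const &s,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  int const m = q.size(), n = s.size();
  double const NEG = -1e18;
  // rows: query (i), cols: subject (j)
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // gap in subject (vertical)
  // F: gap in query (horizontal), computed along the row
  std::vector<signed char> tb((m + 1) * (n + 1), 0); // 0 stop,1 diag,2 up,3 left
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    double F = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double const sub = Hprev[j - 1] +
        ((q[i - 1] == s[j - 1]) ? match : mismatch);
      double const e = std::max(Hprev[j] + gap_open + gap_extend,
                                Eprev[j] + gap_extend);
      F = std::max(Hcur[j - 1] + gap_open + gap_extend, F + gap_extend);
      double h = 0.0;
      signed char dir = 0;
      if (sub > h) { h = sub; dir = 1; }
      if (e > h)   { h = e;   dir = 2; }
      if (F > h)   { h = F;   dir = 3; }
      Hcur[j] = h;
      Ecur[j] = e;
      tb[(size_t)i * (n + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback (approximate path through H states; gap runs follow the
  // stored per-cell direction, which is exact for score and end points and
  // recovers a start point of an optimal alignment)
  int i = bi, j = bj;
  int qe = bi, se = bj, qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    signed char d = tb[(size_t)i * (n + 1) + j];
    if (d == 0) break;
    qs = i; ss = j;
    if (d == 1) { --i; --j; }
    else if (d == 2) { --i; }
    else { --j; }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se);
}

// Per-column majority consensus over equal-length sequences; ties broken
// alphabetically (A < C < G < N < T by character code).
// [[Rcpp::export(name = ".consensus_cpp")]]
std::string consensus_cpp(std::vector<std::string> const &seqs) {
  if (seqs.empty()) return "";
  size_t const L = seqs[0].size();
  std::string out(L, 'N');
  for (size_t p = 0; p < L; ++p) {
    int counts[256] = {0};
    for (auto const &s : seqs) counts[(unsigned char)s[p]]++;
    int bestc = 0;
    unsigned char bestch = 0;
    for (int c = 0; c < 256; ++c) {
      if (counts[c] > bestc) { bestc = counts[c]; bestch = (unsigned char)c; }
    }
    out[p] = (char)bestch;
  }
  return out;
}
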