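#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a lexicographic (score, matches)
// objective: maximize alignment score first, then the number of identical
// aligned residue pairs among co-optimal alignments. A gap run of length g
// costs gap_open + g * gap_extend (both <= 0). No free end gaps.
namespace {

struct SM {
  double s;
  int m;
};

const double NEG = -1e300;

inline bool better(const SM &a, const SM &b) {
  if (a.s != b.s) return a.s > b.s;
  return a.m > b.m;
}

inline SM pick(const SM &a, const SM &b) { return better(a, b) ? a : b; }

inline SM shift(const SM &a, double ds) {
  SM r;
  r.s = (a.s <= NEG / 2) ? a.s : a.s + ds;
  r.m = a.m;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_global_align(const std::string &a, const std::string &b,
                      double match, double mismatch, double gap_open,
                      double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double open_step = gap_open + gap_extend;

  // rolling rows over j = 0..m for states M (pair), E (gap in a), F (gap in b)
  std::vector<SM> Mprev(m + 1), Eprev(m + 1), Fprev(m + 1);
  std::vector<SM> Mcur(m + 1), Ecur(m + 1), Fcur(m + 1);

  Mprev[0] = {0.0, 0};
  Eprev[0] = {NEG, 0};
  Fprev[0] = {NEG, 0};
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = {NEG, 0};
    Eprev[j] = {gap_open + j * gap_extend, 0};
    Fprev[j] = {NEG, 0};
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = {NEG, 0};
    Ecur[0] = {NEG, 0};
    Fcur[0] = {gap_open + i * gap_extend, 0};
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      SM diag = pick(Mprev[j - 1], pick(Eprev[j - 1], Fprev[j - 1]));
      SM mm = shift(diag, eq ? match : mismatch);
      if (mm.s > NEG / 2 && eq) mm.m += 1;
      Mcur[j] = mm;
      // E: gap in a, consume b[j-1] (move left -> right)
      Ecur[j] = pick(shift(pick(Mcur[j - 1], Fcur[j - 1]), open_step),
                     shift(Ecur[j - 1], gap_extend));
      // F: gap in b, consume a[i-1] (move top -> bottom)
      Fcur[j] = pick(shift(pick(Mprev[j], Eprev[j]), open_step),
                     shift(Fprev[j], gap_extend));
    }
    std::swap(Mprev, Mcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  SM best = pick(Mprev[m], pick(Eprev[m], Fprev[m]));
  return List::create(_["score"] = best.s, _["matches"] = best.m);
}
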