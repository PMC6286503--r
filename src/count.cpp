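#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window matcher over bit-encoded sequences. Genome letters carry
// the bit of their concrete base (ambiguity letters encode to 0); pattern
// letters carry the union mask of their IUPAC set. A window matches when
// every genome bit intersects the corresponding pattern mask, so ambiguous
// genome letters never match, not even against N.

// [[Rcpp::export]]
int count_windows_(IntegerVector codes, IntegerVector mask) {
  const int G = codes.size(), L = mask.size();
  if (L == 0 || L > G) return 0;
  int n = 0;
  const int *c = INTEGER(codes), *m = INTEGER(mask);
  for (int i = 0; i + L <= G; ++i) {
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      if ((c[i + j] & m[j]) == 0) { ok = false; break; }
    }
    if (ok) ++n;
  }
  return n;
}

// 1-based start positions of all matching windows (overlaps allowed).

// [[Rcpp::export]]
IntegerVector match_positions_(IntegerVector codes, IntegerVector mask) {
  const int G = codes.size(), L = mask.size();
  std::vector<int> hits;
  if (L == 0 || L > G) return IntegerVector(0);
  const int *c = INTEGER(codes), *m = INTEGER(mask);
  for (int i = 0; i + L <= G; ++i) {
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      if ((c[i + j] & m[j]) == 0) { ok = false; break; }
    }
    if (ok) hits.push_back(i + 1);
  }
  return wrap(hits);
}
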