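#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped overlap scan between two equal-length reads over every shift
// whose overlap meets the coverage floor. Reads here are fragments of a
// shared repeat unit differing by substitutions only, so the optimal
// overlap alignment lies on a single diagonal; scanning all admissible
// diagonals is an exact banded alignment for this error model.
//
// For shift d >= 0 the overlap aligns a[d..L-1] with b[0..L-1-d];
// d < 0 swaps the roles. identity = matches / overlap_len,
// coverage = overlap_len / L, weight = identity * coverage.
//
// [[Rcpp::export]]
List scan_candidate_pairs(CharacterVector seqs, IntegerVector ia,
                          IntegerVector ib, double min_identity,
                          double min_coverage) {
  const int np = ia.size();
  std::vector<std::string> s(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  const int L = s.empty() ? 0 : (int)s[0].size();
  // smallest admissible overlap, hence largest |shift|
  int min_ov = (int)std::ceil(min_coverage * L - 1e-9);
  if (min_ov < 1) min_ov = 1;
  const int max_shift = L - min_ov;

  LogicalVector keep(np);
  NumericVector weight(np), identity(np), coverage(np);
  IntegerVector shift(np);

  for (int p = 0; p < np; ++p) {
    const std::string &a = s[ia[p] - 1];
    const std::string &b = s[ib[p] - 1];
    double best_w = -1.0, best_id = 0.0, best_cov = 0.0;
    int best_d = 0;
    for (int d = -max_shift; d <= max_shift; ++d) {
      const int ov = L - (d >= 0 ? d : -d);
      const char *pa = a.data() + (d >= 0 ? d : 0);
      const char *pb = b.data() + (d >= 0 ? 0 : -d);
      int matches = 0;
      for (int i = 0; i < ov; ++i)
        if (pa[i] == pb[i] && pa[i] != 'N') ++matches;
      const double id = (double)matches / ov;
      const double cov = (double)ov / L;
      if (id >= min_identity) {
        const double w = id * cov;
        if (w > best_w) {
          best_w = w; best_id = id; best_cov = cov; best_d = d;
        }
      }
    }
    keep[p] = best_w >= 0;
    weight[p] = best_w < 0 ? NA_REAL : best_w;
    identity[p] = best_w < 0 ? NA_REAL : best_id;
    coverage[p] = best_w < 0 ? NA_REAL : best_cov;
    shift[p] = best_w < 0 ? NA_INTEGER : best_d;
  }
  return List::create(_["keep"] = keep, _["weight"] = weight,
                      _["identity"] = identity, _["coverage"] = coverage,
                      _["shift"] = shift);
}
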