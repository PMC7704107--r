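#include <Rcpp.h>
using namespace Rcpp;

// Maximum one-to-one pairing of two sorted spike trains under an inclusive
// tolerance window. A greedy two-pointer sweep over sorted trains attains
// the bipartite optimum for interval ("within delta") adjacency: whenever
// the earliest unmatched spikes of the two trains are within delta, pairing
// them is never worse than any alternative (exchange argument), and ties
// between equidistant candidates resolve toward the earlier spike.

// [[Rcpp::export(name = ".match_pairs_cpp")]]
IntegerMatrix match_pairs_cpp(NumericVector t1, NumericVector t2, double delta) {
  R_xlen_t n1 = t1.size(), n2 = t2.size();
  std::vector<int> ia, ib;
  R_xlen_t i = 0, j = 0;
  while (i < n1 && j < n2) {
    double d = t1[i] - t2[j];
    if (std::abs(d) <= delta) {
      ia.push_back((int)(i + 1));
      ib.push_back((int)(j + 1));
      ++i; ++j;
    } else if (d < 0) {
      ++i;
    } else {
      ++j;
    }
  }
  IntegerMatrix out((int)ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k];
    out(k, 1) = ib[k];
  }
  return out;
}

// [[Rcpp::export(name = ".count_matches_cpp")]]
int count_matches_cpp(NumericVector t1, NumericVector t2, double delta) {
  R_xlen_t n1 = t1.size(), n2 = t2.size();
  int n = 0;
  R_xlen_t i = 0, j = 0;
  while (i < n1 && j < n2) {
    double d = t1[i] - t2[j];
    if (std::abs(d) <= delta) { ++n; ++i; ++j; }
    else if (d < 0) ++i;
    else ++j;
  }
  return n;
}
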