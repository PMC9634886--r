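#include <Rcpp.h>
using namespace Rcpp;

// Convolution of two aggregated isotopic distributions.
//
// Each distribution is stored per extra-nucleon index as a pair of vectors:
// p[k]  probability of carrying k extra nucleons,
// s[k]  probability-weighted sum of extra mass (Da) at k, so the cluster
//       centroid offset is s[k]/p[k].
// For independent molecules the joint distribution is the convolution of p,
// and s convolves as s12 = conv(s1, p2) + conv(p1, s2).
//
// States below `prune` relative to the maximum probability are trimmed from
// both ends (interior states are kept to preserve exact index spacing); the
// returned `offset` counts how many leading states were dropped.
// [[Rcpp::export]]
List conv_aggregated(NumericVector p1, NumericVector s1,
                     NumericVector p2, NumericVector s2,
                     double prune) {
  const int n1 = p1.size(), n2 = p2.size();
  const int n = n1 + n2 - 1;
  NumericVector p(n), s(n);
  for (int i = 0; i < n1; ++i) {
    const double pi = p1[i], si = s1[i];
    if (pi == 0.0 && si == 0.0) continue;
    for (int j = 0; j < n2; ++j) {
      p[i + j] += pi * p2[j];
      s[i + j] += pi * s2[j] + si * p2[j];
    }
  }
  double pmax = 0.0;
  for (int i = 0; i < n; ++i) if (p[i] > pmax) pmax = p[i];
  const double thr = prune * pmax;
  int first = 0, last = n - 1;
  while (first < last && p[first] <= thr) ++first;
  while (last > first && p[last] <= thr) --last;
  return List::create(_["p"] = NumericVector(p.begin() + first, p.begin() + last + 1),
                      _["s"] = NumericVector(s.begin() + first, s.begin() + last + 1),
                      _["offset"] = first);
}
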