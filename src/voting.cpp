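#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Voting-map accumulation over matched dense-SIFT feature pairs.
//
// For every pair (f in a query patch, g in the test image) assigned to the
// same visual word k, a vote of weight d(k) is cast at the implied target
// centroid  L(c_D) = L(g) - s * (L(f) - L(c_Qm)),  rounded half-up per axis;
// votes falling outside the image are discarded. One map per scaling factor
// is accumulated. This is the literal quadruple loop (scales x words x
// query features x test features) organized through an inverted index on the
// visual words, which changes only the enumeration order of the pairs.
//
// q_word/t_word are 1-based word assignments; q_dr/q_dc are the displacement
// L(f) - L(c_Qm) per query feature; t_r/t_c the 0-based test feature
// locations; d the per-word vote weight.
// [[Rcpp::export]]
List cpp_vote_maps(IntegerVector q_word, NumericVector q_dr, NumericVector q_dc,
                   IntegerVector t_word, IntegerVector t_r, IntegerVector t_c,
                   NumericVector d, NumericVector scales, int height, int width) {
  const int K = d.size();
  const int ns = scales.size();
  const R_xlen_t npix = (R_xlen_t)height * width;

  // inverted index: feature ids per word
  std::vector<std::vector<int>> q_by_word(K), t_by_word(K);
  for (int i = 0; i < q_word.size(); ++i) {
    int k = q_word[i] - 1;
    if (k >= 0 && k < K) q_by_word[k].push_back(i);
  }
  for (int i = 0; i < t_word.size(); ++i) {
    int k = t_word[i] - 1;
    if (k >= 0 && k < K) t_by_word[k].push_back(i);
  }

  NumericVector maps(npix * ns);
  double discarded = 0.0;

  for (int si = 0; si < ns; ++si) {
    const double s = scales[si];
    double* map = REAL(maps) + npix * si;
    for (int k = 0; k < K; ++k) {
      const std::vector<int>& qs = q_by_word[k];
      const std::vector<int>& ts = t_by_word[k];
      if (qs.empty() || ts.empty()) continue;
      const double w = d[k];
      for (size_t qi = 0; qi < qs.size(); ++qi) {
        const double sdr = s * q_dr[qs[qi]];
        const double sdc = s * q_dc[qs[qi]];
        for (size_t ti = 0; ti < ts.size(); ++ti) {
          const int r = (int)std::floor((double)t_r[ts[ti]] - sdr + 0.5);
          const int c = (int)std::floor((double)t_c[ts[ti]] - sdc + 0.5);
          if (r < 0 || r >= height || c < 0 || c >= width) {
            discarded += 1.0;
            continue;
          }
          map[(R_xlen_t)c * height + r] += w;
        }
      }
    }
  }

  maps.attr("dim") = IntegerVector::create(height, width, ns);
  return List::create(_["maps"] = maps, _["n_discarded"] = discarded);
}
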