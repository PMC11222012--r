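#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Synchronization likelihood between all channel pairs.
//
// Each channel is time-delay embedded (dimension m, lag l). For every
// reference time i (stride apart), candidate recurrences are the embedded
// points j with w1 < |i - j| <= w2 (Theiler-corrected two-sided window).
// The per-channel, per-time critical distance is set by rank selection so
// that exactly k = ceil(p_ref * n_candidates) candidates fall within it;
// the pairwise synchronization likelihood at time i is the fraction of
// channel-x recurrences that are simultaneously channel-y recurrences,
// averaged over reference times. For independent signals the expectation is
// k / n_candidates (~ p_ref); for identical signals it is 1.
//
// X: channels x samples matrix. Returns a symmetric matrix with zero
// diagonal, entries in [0, 1].
// [[Rcpp::export]]
NumericMatrix sl_matrix_cpp(NumericMatrix X, int m, int lag, int w1, int w2,
                            double p_ref, int stride) {
  const int nch = X.nrow();
  const int ns = X.ncol();
  const int n_emb = ns - (m - 1) * lag;
  if (m < 2 || lag < 1 || stride < 1) stop("need m >= 2, lag >= 1, stride >= 1");
  if (w1 < 0 || w2 <= w1) stop("need 0 <= w1 < w2");
  if (p_ref <= 0.0 || p_ref >= 1.0) stop("p_ref must lie in (0, 1)");
  if (n_emb < 2 * w2 + 2)
    stop("epoch too short for SL: need more than " +
         std::to_string((m - 1) * lag + 2 * w2 + 1) +
         " samples for (m, lag, w2) = (" + std::to_string(m) + ", " +
         std::to_string(lag) + ", " + std::to_string(w2) + ")");

  // reference points with a full window on both sides
  std::vector<int> refs;
  for (int i = w2; i <= n_emb - 1 - w2; i += stride) refs.push_back(i);
  const int nref = refs.size();
  const int ncand = 2 * (w2 - w1);
  const int k = std::max(1, (int)std::ceil(p_ref * ncand));

  // neighbor sets: per channel, per reference point, k sorted indices
  std::vector<std::vector<int>> nbr((size_t)nch * nref);
  std::vector<std::pair<double, int>> cand(ncand);

  std::vector<double> emb((size_t)n_emb * m);

  for (int c = 0; c < nch; ++c) {
    // contiguous time-delay embedding of this channel
    for (int t = 0; t < n_emb; ++t)
      for (int e = 0; e < m; ++e)
        emb[(size_t)t * m + e] = X(c, t + e * lag);
    for (int r = 0; r < nref; ++r) {
      const int i = refs[r];
      const double *vi = &emb[(size_t)i * m];
      int nc = 0;
      for (int side = 0; side < 2; ++side) {
        for (int d = w1 + 1; d <= w2; ++d) {
          const int j = side == 0 ? i - d : i + d;
          const double *vj = &emb[(size_t)j * m];
          double s = 0.0;
          for (int e = 0; e < m; ++e) {
            const double diff = vi[e] - vj[e];
            s += diff * diff;
          }
          cand[nc++] = std::make_pair(s, j);
        }
      }
      std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
      std::vector<int> &v = nbr[(size_t)c * nref + r];
      v.resize(k);
      // collect the k smallest (ties resolved by the pair's index order)
      std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
      for (int q = 0; q < k; ++q) v[q] = cand[q].second;
      std::sort(v.begin(), v.end());
    }
  }

  NumericMatrix out(nch, nch);
  for (int a = 0; a < nch; ++a) {
    for (int b = a + 1; b < nch; ++b) {
      double acc = 0.0;
      for (int r = 0; r < nref; ++r) {
        const std::vector<int> &va = nbr[(size_t)a * nref + r];
        const std::vector<int> &vb = nbr[(size_t)b * nref + r];
        int ia = 0, ib = 0, common = 0;
        while (ia < k && ib < k) {
          if (va[ia] == vb[ib]) { ++common; ++ia; ++ib; }
          else if (va[ia] < vb[ib]) ++ia;
          else ++ib;
        }
        acc += (double)common / k;
      }
      out(a, b) = out(b, a) = acc / nref;
    }
  }
  return out;
}
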