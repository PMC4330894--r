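// Synchronization-likelihood kernel.
//
// For each channel the 1-D signal is time-delay embedded (dimension m,
// lag l).  For every reference time i, the critical distance eps(i) is
// the empirical p_ref-quantile of Euclidean distances to embedded
// vectors j inside the two-sided window w1 < |i - j| < w2 (w1 is the
// Theiler window).  Squared distances are derived from the Gram matrix
// of the embedding (computed by BLAS on the R side):
// d2(i,j) = G(i,i) + G(j,j) - 2 G(j,i).  Simultaneous recurrences of
// two channels, counted over the same windows and normalised by the
// realised per-channel recurrence counts, give SL.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List recsets_from_gram(NumericMatrix G, int w1, int w2, double p_ref) {
  const int T = G.nrow();
  if (T <= w1 + 1) stop("epoch too short for the embedding window");
  const double* g = REAL(G);
  std::vector<double> diag(T);
  for (int i = 0; i < T; ++i) diag[i] = g[static_cast<size_t>(i) * T + i];

  std::vector<int> idx;
  idx.reserve(static_cast<size_t>(T) * 24);
  IntegerVector off(T + 1), nwv(T);
  NumericVector eps(T);
  std::vector<double> dist, tmp;
  dist.reserve(2 * static_cast<size_t>(w2));

  for (int i = 0; i < T; ++i) {
    const int l1 = std::max(0, i - w2 + 1), h1 = i - w1 - 1;
    const int l2 = i + w1 + 1, h2 = std::min(T - 1, i + w2 - 1);
    const int n1 = (h1 >= l1) ? h1 - l1 + 1 : 0;
    const int n2 = (h2 >= l2) ? h2 - l2 + 1 : 0;
    const int n_w = n1 + n2;
    if (n_w == 0)
      stop("empty recurrence window: check w1/w2 against epoch length");
    nwv[i] = n_w;
    dist.resize(n_w);
    const double* gi = g + static_cast<size_t>(i) * T; // column i = G(., i)
    const double di = diag[i];
    int t = 0;
    for (int j = l1; j <= h1; ++j, ++t) dist[t] = di + diag[j] - 2.0 * gi[j];
    for (int j = l2; j <= h2; ++j, ++t) dist[t] = di + diag[j] - 2.0 * gi[j];

    int nhit = std::max(1, static_cast<int>(std::lround(p_ref * n_w)));
    if (nhit > n_w) nhit = n_w;
    tmp = dist;
    std::nth_element(tmp.begin(), tmp.begin() + (nhit - 1), tmp.end());
    const double e2 = tmp[nhit - 1];
    eps[i] = std::sqrt(std::max(e2, 0.0));
    for (t = 0; t < n1; ++t)
      if (dist[t] <= e2) idx.push_back(l1 + t);
    for (; t < n_w; ++t)
      if (dist[t] <= e2) idx.push_back(l2 + (t - n1));
    off[i + 1] = static_cast<int>(idx.size());
  }
  return List::create(_["idx"] = IntegerVector(idx.begin(), idx.end()),
                      _["off"] = off, _["n_w"] = nwv, _["eps"] = eps);
}

// SL_i = H_i * p_ref * N_w / (n_k(i) * n_q(i)): the simultaneous-
// recurrence count normalised by the realised per-channel recurrence
// counts, so independent channels give exactly p_ref in expectation
// (the nominal p_ref * N_w normalisation inherits the integer rounding
// of the recurrence quantile) and identical channels give 1.
// [[Rcpp::export]]
NumericMatrix sl_from_recsets(List recsets, double p_ref) {
  const int C = recsets.size();
  if (C < 2) stop("need at least 2 channels");
  std::vector<const int*> idx(C), off(C);
  IntegerVector nwv;
  for (int c = 0; c < C; ++c) {
    List rs = recsets[c];
    IntegerVector iv = rs["idx"], ov = rs["off"];
    idx[c] = INTEGER(iv);
    off[c] = INTEGER(ov);
    if (c == 0) nwv = rs["n_w"];
  }
  List rs0 = recsets[0];
  IntegerVector off0 = rs0["off"];
  const int T = off0.size() - 1;

  NumericMatrix sl(C, C);
  for (int k = 0; k < C; ++k) {
    for (int q = k + 1; q < C; ++q) {
      double acc = 0.0;
      const int* ik = idx[k];
      const int* iq = idx[q];
      const int* ok = off[k];
      const int* oq = off[q];
      for (int i = 0; i < T; ++i) {
        int a = ok[i], ae = ok[i + 1];
        int b = oq[i], be = oq[i + 1];
        const double nk = ae - a, nq = be - b;
        int h = 0;
        while (a < ae && b < be) {
          if (ik[a] < iq[b]) ++a;
          else if (ik[a] > iq[b]) ++b;
          else { ++h; ++a; ++b; }
        }
        acc += h * p_ref * nwv[i] / (nk * nq);
      }
      double v = acc / T;
      if (v > 1.0) v = 1.0;
      if (v < 0.0) v = 0.0;
      sl(k, q) = v;
      sl(q, k) = v;
    }
  }
  return sl;
}
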