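#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura edit distance between two sorted spike-time vectors.
// Insertion/deletion cost 1, shift cost q * |dt| (q in 1/s, times in s).
// Standard O(nx * ny) dynamic programme with two rolling rows.
// [[Rcpp::export]]
double vp_distance_cpp(NumericVector x, NumericVector y, double q) {
  const int nx = x.size(), ny = y.size();
  if (nx == 0) return (double)ny;
  if (ny == 0) return (double)nx;
  std::vector<double> prev(ny + 1), cur(ny + 1);
  for (int j = 0; j <= ny; ++j) prev[j] = j;
  for (int i = 1; i <= nx; ++i) {
    cur[0] = i;
    const double xi = x[i - 1];
    for (int j = 1; j <= ny; ++j) {
      double shift = prev[j - 1] + q * std::fabs(xi - y[j - 1]);
      double del   = prev[j] + 1.0;
      double ins   = cur[j - 1] + 1.0;
      double m = shift < del ? shift : del;
      cur[j] = m < ins ? m : ins;
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

// Discrete-time coupled point-process panel. Each channel fires per 1-bin
// Bernoulli draws with instantaneous rate = base rate multiplied by the
// strength of every incoming edge whose source fired `lag` bins earlier.
// Rates capped at 1 spike/bin; sustained rates above `rate_limit` Hz abort.
// Uses R's RNG so set.seed() governs the draws.
// [[Rcpp::export]]
IntegerMatrix panel_sim_cpp(int n_bins, int n_channels,
                            NumericVector base_rate_hz, double bin_s,
                            IntegerVector edge_src, IntegerVector edge_tgt,
                            IntegerVector edge_lag, NumericVector edge_strength,
                            double rate_limit_hz, int sustain_bins) {
  IntegerMatrix spikes(n_bins, n_channels);
  const int n_edges = edge_src.size();
  std::vector<int> hot(n_channels, 0);
  for (int t = 0; t < n_bins; ++t) {
    for (int c = 0; c < n_channels; ++c) {
      double lam = base_rate_hz[c];
      for (int e = 0; e < n_edges; ++e) {
        if (edge_tgt[e] != c) continue;
        int ts = t - edge_lag[e];
        if (ts >= 0 && spikes(ts, edge_src[e]) > 0) lam *= edge_strength[e];
      }
      if (lam > rate_limit_hz) {
        if (++hot[c] > sustain_bins)
          stop("rate explosion on channel %d (> %.0f Hz sustained); reduce coupling strengths",
               c + 1, rate_limit_hz);
      } else hot[c] = 0;
      double p = lam * bin_s;
      if (p > 1.0) p = 1.0;
      spikes(t, c) = (unif_rand() < p) ? 1 : 0;
    }
  }
  return spikes;
}

// Direct-form II transposed IIR filter (single pass), a[0] assumed 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = b[0] * x[i] + (nw > 0 ? w[0] : 0.0);
    for (int k = 1; k <= nw; ++k) {
      double wk = 0.0;
      if (k < nb) wk += b[k] * x[i];
      if (k < na) wk -= a[k] * yi;
      if (k < nw) wk += w[k];
      w[k - 1] = wk;
    }
    y[i] = yi;
  }
  return y;
}
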