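#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-tau correlator with symmetric normalization.
//
// Lag grid: the first `m` lags at the base sampling interval, then the
// series is re-binned by factors of two and lags m/2+1 .. m evaluated
// at each level, giving m/2 points per octave (m = 16 -> 8 per octave).
// At every lag the estimator is
//   G(k) = mean_t( x[t] y[t+k] ) / ( mean(x over window) *
//                                    mean(y over shifted window) ) - 1,
// the fluctuation correlation; means are taken over the overlapping
// window at each lag (symmetric normalization, suppresses drift bias).

static void multitau_one(const double *x0, const double *y0, int N,
                         int m, double maxLag,
                         std::vector<double> &lag,
                         std::vector<double> &G,
                         std::vector<double> &nsamp,
                         bool firstPair, bool &bad) {
  std::vector<double> xs(x0, x0 + N), ys(y0, y0 + N);
  int n = N;
  double bin = 1.0;
  int level = 0;
  size_t idx = 0;
  for (;;) {
    int k1 = (level == 0) ? 1 : m / 2 + 1;
    for (int k = k1; k <= m; ++k) {
      double lagval = k * bin;
      if (lagval > maxLag) return;
      int M = n - k;
      if (M < 8) return;
      double sxy = 0.0, sx = 0.0, sy = 0.0;
      const double *xp = xs.data(), *yp = ys.data();
      for (int t = 0; t < M; ++t) {
        sxy += xp[t] * yp[t + k];
        sx += xp[t];
        sy += yp[t + k];
      }
      double mx = sx / M, my = sy / M;
      if (mx <= 0.0 || my <= 0.0) { bad = true; return; }
      double g = (sxy / M) / (mx * my) - 1.0;
      if (firstPair) {
        lag.push_back(lagval);
        G.push_back(g);
        nsamp.push_back((double)M);
      } else {
        if (idx >= G.size()) return;  // shorter series: stop
        G[idx] += g;
        nsamp[idx] += (double)M;
      }
      ++idx;
    }
    // re-bin by two (averaging keeps normalization unchanged)
    int nh = n / 2;
    if (nh < m + 8) return;
    for (int t = 0; t < nh; ++t) {
      xs[t] = 0.5 * (xs[2 * t] + xs[2 * t + 1]);
      ys[t] = 0.5 * (ys[2 * t] + ys[2 * t + 1]);
    }
    n = nh;
    bin *= 2.0;
    ++level;
  }
}

// Average of per-column-pair multi-tau correlations.  `ia`, `ib` are
// 0-based column indices into `mat` (rows = lines, cols = pixels);
// pair k correlates column ia[k] (earlier time) against ib[k].
// Returns the lag grid in units of the sampling interval, the mean G
// over pairs, total samples per lag, and the number of pairs skipped
// for having a non-positive mean.
// [[Rcpp::export(name = ".cpp_multitau_pairs")]]
List cpp_multitau_pairs(NumericMatrix mat, IntegerVector ia,
                        IntegerVector ib, int m, double maxLag) {
  const int N = mat.nrow();
  std::vector<double> lag, G, nsamp;
  int used = 0, skipped = 0;
  for (int k = 0; k < ia.size(); ++k) {
    bool bad = false;
    std::vector<double> Gk, nk;
    if (used == 0) {
      multitau_one(&mat(0, ia[k]), &mat(0, ib[k]), N, m, maxLag,
                   lag, G, nsamp, true, bad);
      if (bad) { lag.clear(); G.clear(); nsamp.clear(); ++skipped; }
      else ++used;
    } else {
      std::vector<double> dummyLag;
      bool bad2 = false;
      // accumulate into existing grid
      size_t before = G.size();
      std::vector<double> Gsave(G), nsave(nsamp);
      multitau_one(&mat(0, ia[k]), &mat(0, ib[k]), N, m, maxLag,
                   dummyLag, G, nsamp, false, bad2);
      if (bad2) { G = Gsave; nsamp = nsave; ++skipped; }
      else { ++used; (void)before; }
    }
  }
  NumericVector lagOut(lag.begin(), lag.end());
  NumericVector Gout(G.begin(), G.end());
  NumericVector nOut(nsamp.begin(), nsamp.end());
  if (used > 0) for (int i = 0; i < Gout.size(); ++i) Gout[i] /= used;
  return List::create(_["lag"] = lagOut, _["G"] = Gout, _["n"] = nOut,
                      _["pairs_used"] = used, _["pairs_skipped"] = skipped);
}

// Spatial cross-correlation profile: for each pixel separation delta,
// the symmetrically normalized cross-correlation of columns i and
// i + delta at temporal lag `lag` (in lines), averaged over all i and
// over both orientations.
// [[Rcpp::export(name = ".cpp_spatial_profile")]]
NumericVector cpp_spatial_profile(NumericMatrix mat, IntegerVector deltas,
                                  int lag) {
  const int N = mat.nrow(), P = mat.ncol();
  const int M = N - lag;
  NumericVector out(deltas.size());
  for (int d = 0; d < deltas.size(); ++d) {
    const int delta = deltas[d];
    double acc = 0.0;
    int npairs = 0;
    for (int i = 0; i + delta < P; ++i) {
      for (int dir = 0; dir < (delta == 0 ? 1 : 2); ++dir) {
        const double *x = dir == 0 ? &mat(0, i) : &mat(0, i + delta);
        const double *y = dir == 0 ? &mat(0, i + delta) : &mat(0, i);
        double sxy = 0.0, sx = 0.0, sy = 0.0;
        for (int t = 0; t < M; ++t) {
          sxy += x[t] * y[t + lag];
          sx += x[t];
          sy += y[t + lag];
        }
        double mx = sx / M, my = sy / M;
        if (mx <= 0.0 || my <= 0.0) continue;
        acc += (sxy / M) / (mx * my) - 1.0;
        ++npairs;
      }
    }
    out[d] = npairs > 0 ? acc / npairs : NA_REAL;
  }
  return out;
}
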