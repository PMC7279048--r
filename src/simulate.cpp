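#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brownian photon-stream simulator for one species of a scanned-line
// acquisition.  Molecule positions are updated once per line period
// (pixel dwell << line period, so intra-line motion is negligible at
// membrane-protein diffusion coefficients).  The beam is a 2D Gaussian
// detection profile exp(-2 r^2 / w^2) centred on y = 0; pixel centres
// sit at x = (p + 0.5) * pixelSize.  Photon counts per dwell are
// Poisson with rate = sum over molecules of brightness * profile, then
// split multinomially over spectral channels.  Counts accumulate into
// `counts` (length nLines*nPixels*nChannels, R column-major order
// [line, pixel, channel]); `totals` (same minus channel axis) receives
// the pre-split Poisson draws when keepTotals is true.
//
// Uses the R RNG: seeding is controlled from R with set.seed().

// [[Rcpp::export(name = ".cpp_simulate_species")]]
List cpp_simulate_species(IntegerVector counts,
                          IntegerVector totals,
                          bool keepTotals,
                          int nLines, int nPixels, int nChannels,
                          double pixelSize, double lineLength,
                          double linePeriod,
                          double waist, double D, double brightness,
                          int nMolecules, double boxX, double boxY,
                          NumericVector channelProb,
                          bool mobile, bool trackFirst,
                          NumericMatrix initPositions) {
  if (nMolecules <= 0)
    return List::create(_["track"] = R_NilValue);

  const double x0 = lineLength / 2.0 - boxX / 2.0;  // box x-range
  const double y0 = -boxY / 2.0;
  const double sd = mobile ? std::sqrt(2.0 * D * linePeriod) : 0.0;
  const double cutoff = 3.0 * waist;        // beam profile support
                                            // (exp(-18) ~ 1.5e-8 truncation)
  const double cut2 = cutoff * cutoff;
  const double inv_w2 = 2.0 / (waist * waist);

  std::vector<double> mx(nMolecules), my(nMolecules);
  const bool haveInit = initPositions.nrow() == nMolecules;
  for (int i = 0; i < nMolecules; ++i) {
    if (haveInit) { mx[i] = initPositions(i, 0); my[i] = initPositions(i, 1); }
    else {
      mx[i] = x0 + unif_rand() * boxX;
      my[i] = y0 + unif_rand() * boxY;
    }
  }

  NumericMatrix track;
  if (trackFirst) track = NumericMatrix(nLines, 2);

  std::vector<double> rate(nPixels, 0.0);
  std::vector<int> touched;
  touched.reserve(nPixels);
  std::vector<double> prob(channelProb.begin(), channelProb.end());

  for (int l = 0; l < nLines; ++l) {
    // advance molecules by one line period (periodic boundaries)
    if (mobile) {
      for (int i = 0; i < nMolecules; ++i) {
        mx[i] += norm_rand() * sd;
        my[i] += norm_rand() * sd;
        mx[i] -= boxX * std::floor((mx[i] - x0) / boxX);
        my[i] -= boxY * std::floor((my[i] - y0) / boxY);
      }
    }
    if (trackFirst) { track(l, 0) = mx[0]; track(l, 1) = my[0]; }

    // accumulate detection rate per pixel; the Gaussian along x is
    // evaluated by the incremental recurrence
    //   exp(-a (d+h)^2) = exp(-a d^2) * exp(-a (2 d h + h^2)),
    // whose update factor is itself geometric in p (two multiplies per
    // pixel instead of one exp call)
    const double h = pixelSize;
    const double stepFac = std::exp(-inv_w2 * 2.0 * h * h);  // ratio update
    for (int i = 0; i < nMolecules; ++i) {
      const double y2 = my[i] * my[i];
      if (y2 > cut2) continue;
      int pmin = (int)std::ceil((mx[i] - cutoff) / pixelSize - 0.5);
      int pmax = (int)std::floor((mx[i] + cutoff) / pixelSize - 0.5);
      if (pmin < 0) pmin = 0;
      if (pmax >= nPixels) pmax = nPixels - 1;
      if (pmin > pmax) continue;
      const double amp = brightness * std::exp(-y2 * inv_w2);
      double d0 = (pmin + 0.5) * pixelSize - mx[i];
      double e = std::exp(-inv_w2 * d0 * d0);
      double f = std::exp(-inv_w2 * (2.0 * d0 * h + h * h));
      for (int p = pmin; p <= pmax; ++p) {
        if (rate[p] == 0.0) touched.push_back(p);
        rate[p] += amp * e;
        e *= f;
        f *= stepFac;
      }
    }

    // Poisson draw per dwell, multinomial split over channels
    for (size_t k = 0; k < touched.size(); ++k) {
      const int p = touched[k];
      int n = (int)R::rpois(rate[p]);
      rate[p] = 0.0;
      if (n == 0) continue;
      if (keepTotals) totals[l + (R_xlen_t)nLines * p] += n;
      int remaining = n;
      double pleft = 1.0;
      for (int c = 0; c < nChannels - 1 && remaining > 0; ++c) {
        double pc = prob[c] / pleft;
        if (pc > 1.0) pc = 1.0;
        int nc = (int)R::rbinom((double)remaining, pc);
        if (nc > 0)
          counts[l + (R_xlen_t)nLines * (p + (R_xlen_t)nPixels * c)] += nc;
        remaining -= nc;
        pleft -= prob[c];
        if (pleft <= 0.0) break;
      }
      if (remaining > 0)
        counts[l + (R_xlen_t)nLines *
                     (p + (R_xlen_t)nPixels * (nChannels - 1))] += remaining;
    }
    touched.clear();
  }

  return List::create(_["track"] = trackFirst ? (SEXP)track : R_NilValue);
}
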