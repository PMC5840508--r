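#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-coefficient mutual information from bootstrap sub-ensemble averages.
//
// coef:       nTrials x P coefficient matrix (one channel).
// idxByClass: per class (ascending label order), 1-based trial rows of
//             length nAverages * trialsPerAverage, drawn with replacement
//             from that class's training trials by the caller (R owns the
//             RNG; this kernel is deterministic given the indices).
// Returns the plug-in MI (bits) of each coefficient with the class label,
// after averaging each consecutive block of trialsPerAverage rows and
// quantizing the nClasses * nAverages sub-average values into nBins
// equal-width bins over their min-max range. Matches quantizeBins() /
// mutualInformation() in R exactly (same binning expression, P(class)
// uniform by construction).
// [[Rcpp::export]]
NumericVector fold_coef_info(const NumericMatrix& coef, const List& idxByClass,
                             int nAverages, int trialsPerAverage, int nBins) {
  const int P = coef.ncol();
  const int nTrials = coef.nrow();
  const int C = idxByClass.size();
  const int nVals = C * nAverages;
  const int perClass = nAverages * trialsPerAverage;

  std::vector<IntegerVector> idxVecs;
  idxVecs.reserve(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector v = idxByClass[c];
    if (v.size() != perClass)
      stop("index vector for class %d has length %d, expected %d",
           c + 1, (int)v.size(), perClass);
    for (int t = 0; t < perClass; ++t)
      if (v[t] < 1 || v[t] > nTrials) stop("trial index out of range");
    idxVecs.push_back(v);
  }

  NumericVector out(P);
  std::vector<double> vals(nVals);
  std::vector<int> counts(C * nBins);
  const double invPer = 1.0 / trialsPerAverage;
  const double N = (double)nVals;
  const double pc = nAverages / N;  // uniform class probability

  for (int p = 0; p < P; ++p) {
    const double* col = &coef(0, p);
    double mn = R_PosInf, mx = R_NegInf;
    int v = 0;
    for (int c = 0; c < C; ++c) {
      const int* idx = idxVecs[c].begin();
      int pos = 0;
      for (int a = 0; a < nAverages; ++a) {
        double s = 0.0;
        for (int t = 0; t < trialsPerAverage; ++t, ++pos)
          s += col[idx[pos] - 1];
        s *= invPer;
        vals[v++] = s;
        if (s < mn) mn = s;
        if (s > mx) mx = s;
      }
    }
    if (!(mx > mn)) { out[p] = 0.0; continue; }

    std::fill(counts.begin(), counts.end(), 0);
    const double w = nBins / (mx - mn);
    v = 0;
    for (int c = 0; c < C; ++c) {
      for (int a = 0; a < nAverages; ++a, ++v) {
        int b = (int)((vals[v] - mn) * w);
        if (b >= nBins) b = nBins - 1;
        counts[c * nBins + b]++;
      }
    }

    double mi = 0.0;
    for (int b = 0; b < nBins; ++b) {
      int bTot = 0;
      for (int c = 0; c < C; ++c) bTot += counts[c * nBins + b];
      if (bTot == 0) continue;
      const double pb = bTot / N;
      for (int c = 0; c < C; ++c) {
        const int jc = counts[c * nBins + b];
        if (jc == 0) continue;
        const double pj = jc / N;
        mi += pj * std::log2(pj / (pc * pb));
      }
    }
    out[p] = mi;
  }
  return out;
}
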