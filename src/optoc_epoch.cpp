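#include <Rcpp.h>
using namespace Rcpp;

// One online OPTOC pass. The caller supplies the (already randomized)
// presentation order; all randomness stays on the R side.
//
// For input X with winner prototype i (nearest by Euclidean distance):
//  - neighbour test: |X - P_i| <= |A_i - P_i|; neighbours drag the APV
//    towards them with a 1/n running-average step;
//  - the winner prototype always moves towards X with rate
//    (|A_i - P_i| / (|X - P_i| + |A_i - P_i|))^2;
//  - non-neighbours at least as far out as the DPV drag the DPV outward.
// [[Rcpp::export(name = ".optocEpochCpp")]]
List optocEpochCpp(NumericMatrix x, IntegerVector order,
                   NumericMatrix P, NumericMatrix A, NumericMatrix D,
                   IntegerVector nA, IntegerVector nD) {
  const int d = x.ncol();
  const int K = P.nrow();
  NumericMatrix P2(clone(P)), A2(clone(A)), D2(clone(D));
  IntegerVector nA2(clone(nA)), nD2(clone(nD));

  for (int t = 0; t < order.size(); ++t) {
    const int idx = order[t] - 1;

    // winner = nearest prototype, ties to the lower index
    int win = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x(idx, j) - P2(k, j);
        s += diff * diff;
      }
      if (s < best) { best = s; win = k; }
    }

    double dXP = std::sqrt(best);
    double dAP = 0.0, dDP = 0.0;
    for (int j = 0; j < d; ++j) {
      const double da = A2(win, j) - P2(win, j);
      const double dd = D2(win, j) - P2(win, j);
      dAP += da * da;
      dDP += dd * dd;
    }
    dAP = std::sqrt(dAP);
    dDP = std::sqrt(dDP);

    if (dXP <= dAP) {
      nA2[win] += 1;
      const double step = 1.0 / nA2[win];
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        A2(win, j) += step * (x(idx, j) - A2(win, j));
        const double da = A2(win, j) - P2(win, j);
        s += da * da;
      }
      dAP = std::sqrt(s);
    } else if (dXP >= dDP) {
      nD2[win] += 1;
      const double step = 1.0 / nD2[win];
      for (int j = 0; j < d; ++j)
        D2(win, j) += step * (x(idx, j) - D2(win, j));
    }

    // the winner always moves towards the input; patterns outside the
    // dynamic neighbourhood contribute less through the shrinking rate
    const double denom = dXP + dAP;
    if (denom > 0.0) {
      const double alpha = (dAP / denom) * (dAP / denom);
      for (int j = 0; j < d; ++j)
        P2(win, j) += alpha * (x(idx, j) - P2(win, j));
    }
  }
  return List::create(_["P"] = P2, _["A"] = A2, _["D"] = D2,
                      _["nA"] = nA2, _["nD"] = nD2);
}
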