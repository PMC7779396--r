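#include <Rcpp.h>
using namespace Rcpp;

// Leave-one-out CPM engine for tie-free data.
//
// With tie-free columns, leave-one-out ranks follow from full-sample ranks
// by decrementing every rank above the removed subject's, so per fold the
// rank sums and centred sums of squares are the closed-form constants of a
// permutation of 1..m. The Spearman correlation of edge e with the scores
// in fold -i then needs only the inner product of the fold's edge ranks
// with the fold's score ranks. Tied data take the slower R path.
//
// E      n x p subject-by-edge weights
// R      n x p full-sample column ranks of E (no ties)
// srank  full-sample ranks of scores (no ties)
// scores raw scores
// rho_crit selection cut: |rho| > rho_crit  <=>  p < threshold at m = n-1
// [[Rcpp::export(name = ".cpp_loocv")]]
List cpp_loocv(NumericMatrix E, NumericMatrix R, NumericVector srank,
               NumericVector scores, double rho_crit, bool keep_edges) {
  const int n = E.nrow(), p = E.ncol();
  const int m = n - 1;
  const double c0 = m * (m + 1.0) / 2.0;          // sum of 1..m
  const double v0 = m * (m * (double)m - 1.0) / 12.0; // centred SS of 1..m
  const double total_score = sum(scores);

  NumericMatrix pred(n, 2);
  LogicalMatrix empty(n, 2);
  List pos_sets(keep_edges ? n : 0), neg_sets(keep_edges ? n : 0);
  NumericMatrix slopes(n, 2), intercepts(n, 2);

  std::vector<double> sr(n);      // fold score ranks (entry i unused)
  std::vector<double> num(p);
  std::vector<int> pos, neg;
  std::vector<double> strength(n);

  const double *Rp = &R(0, 0);
  for (int i = 0; i < n; ++i) {
    const double sri = srank[i];
    for (int j = 0; j < n; ++j) {
      double s = srank[j];
      sr[j] = (s > sri) ? s - 1.0 : s;
    }
    sr[i] = 0.0; // subject i drops out of every inner product below
    for (int e = 0; e < p; ++e) {
      const double *rc = Rp + (size_t)e * n;
      const double Rie = rc[i];
      double acc = 0.0, sub = 0.0;
      for (int j = 0; j < n; ++j) { // branchless: rank decrement as a mask
        const double s = sr[j];
        acc += rc[j] * s;
        sub += (rc[j] > Rie) * s;
      }
      // Spearman rho of edge e with the scores in fold -i
      num[e] = ((acc - sub) - c0 * c0 / m) / v0;
    }
    pos.clear(); neg.clear();
    for (int e = 0; e < p; ++e) {
      if (num[e] > rho_crit) pos.push_back(e);
      else if (num[e] < -rho_crit) neg.push_back(e);
    }
    const double mean_train = (total_score - scores[i]) / m;

    for (int tail = 0; tail < 2; ++tail) {
      const std::vector<int> &sel = (tail == 0) ? pos : neg;
      if (sel.empty()) {
        pred(i, tail) = mean_train;
        empty(i, tail) = true;
        slopes(i, tail) = 0.0;
        intercepts(i, tail) = mean_train;
        continue;
      }
      std::fill(strength.begin(), strength.end(), 0.0);
      for (size_t k = 0; k < sel.size(); ++k) {
        const double *ec = &E(0, 0) + (size_t)sel[k] * n;
        for (int j = 0; j < n; ++j) strength[j] += ec[j];
      }
      double sx = 0.0;
      for (int j = 0; j < n; ++j) if (j != i) sx += strength[j];
      const double mx = sx / m;
      double sxx = 0.0, sxy = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double d = strength[j] - mx;
        sxx += d * d;
        sxy += d * scores[j];
      }
      double slope, intercept;
      if (sxx == 0.0) {           // constant strengths: flat fallback
        slope = 0.0; intercept = mean_train;
      } else {
        slope = sxy / sxx;
        intercept = mean_train - slope * mx;
      }
      pred(i, tail) = intercept + slope * strength[i];
      slopes(i, tail) = slope;
      intercepts(i, tail) = intercept;
    }
    if (keep_edges) {
      pos_sets[i] = IntegerVector(pos.begin(), pos.end()) + 1;
      neg_sets[i] = IntegerVector(neg.begin(), neg.end()) + 1;
    }
  }
  return List::create(_["pred"] = pred, _["empty"] = empty,
                      _["pos_sets"] = pos_sets, _["neg_sets"] = neg_sets,
                      _["slopes"] = slopes, _["intercepts"] = intercepts);
}
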