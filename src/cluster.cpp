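#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 4-connected component labelling of the pixels of `x` exceeding `thr`
// (or below -thr when side < 0). Labels are 1..K in scan order; 0 elsewhere.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(NumericMatrix x, double thr, int side) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = side >= 0 ? x(i, j) : -x(i, j);
      if (v <= thr || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int qi = pi + di[d], qj = pj + dj[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          double w = side >= 0 ? x(qi, qj) : -x(qi, qj);
          if (w > thr && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Maximum summed statistic over 4-connected supra-threshold clusters of a
// flat matrix (nr x nc, column-major vector). Used inside the sign-flip
// permutation loop.
// [[Rcpp::export(name = ".cc_max_mass")]]
double cc_max_mass(NumericVector x, int nr, int nc, double thr, int side) {
  std::vector<int> lab(nr * nc, 0);
  std::vector<int> stack;
  double best = 0.0;
  int next = 0;
  for (int p0 = 0; p0 < nr * nc; ++p0) {
    double v = side >= 0 ? x[p0] : -x[p0];
    if (v <= thr || lab[p0] != 0) continue;
    ++next;
    double mass = 0.0;
    stack.push_back(p0);
    lab[p0] = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      mass += side >= 0 ? x[p] : -x[p];
      int pi = p % nr, pj = p / nr;
      const int di[4] = {-1, 1, 0, 0};
      const int dj[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int qi = pi + di[d], qj = pj + dj[d];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int q = qi + qj * nr;
        double w = side >= 0 ? x[q] : -x[q];
        if (w > thr && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
    if (mass > best) best = mass;
  }
  return best;
}
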