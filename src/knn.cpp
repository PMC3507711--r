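// HEOM neighbour search for the dirty-example cleaning method.
//
// Distance between rows a and b: sqrt( sum_j d_j^2 ) where d_j is the 0/1
// overlap for a nominal attribute and |a-b|/range for a numeric attribute
// (range taken from the training table; zero range contributes 0).
//
// For each minority row, the k nearest other rows are located; ties at the
// k-th distance are all included. Majority rows appearing in any list are
// "dirty".

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List knn_dirty_cpp(NumericMatrix Xnum, IntegerMatrix Xnom,
                   NumericVector num_range, LogicalVector is_minority,
                   int k, double tie_tol) {
  int n = is_minority.size();
  int pnum = Xnum.ncol(), pnom = Xnom.ncol();
  std::vector<int> mino;
  for (int i = 0; i < n; ++i) if (is_minority[i]) mino.push_back(i);
  int nm = (int)mino.size();

  List nbr_idx(nm), nbr_dist(nm);
  std::vector<bool> dirty(n, false);
  std::vector<double> d2(n);
  std::vector<double> inv_r(pnum);
  for (int q = 0; q < pnum; ++q)
    inv_r[q] = num_range[q] > 0.0 ? 1.0 / num_range[q] : 0.0;

  for (int mi = 0; mi < nm; ++mi) {
    int i = mino[mi];
    std::fill(d2.begin(), d2.end(), 0.0);
    // column-wise sweeps keep memory access sequential
    for (int q = 0; q < pnum; ++q) {
      if (inv_r[q] == 0.0) continue;
      const double* col = &Xnum(0, q);
      const double xi = col[i], ir = inv_r[q];
      for (int j = 0; j < n; ++j) {
        double d = (xi - col[j]) * ir;
        d2[j] += d * d;
      }
    }
    for (int q = 0; q < pnom; ++q) {
      const int* col = &Xnom(0, q);
      const int xi = col[i];
      for (int j = 0; j < n; ++j)
        if (col[j] != xi) d2[j] += 1.0;
    }
    d2[i] = R_PosInf;
    // k-th smallest squared distance among the n-1 others
    std::vector<double> tmp(d2);
    int kk = std::min(k, n - 1);
    std::nth_element(tmp.begin(), tmp.begin() + (kk - 1), tmp.end());
    double cut = tmp[kk - 1] + tie_tol;
    std::vector<int> idx;
    for (int j = 0; j < n; ++j)
      if (j != i && d2[j] <= cut) idx.push_back(j);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (d2[a] != d2[b]) return d2[a] < d2[b];
      return a < b;
    });
    NumericVector dv(idx.size());
    IntegerVector iv(idx.size());
    for (size_t t = 0; t < idx.size(); ++t) {
      iv[t] = idx[t] + 1;  // 1-based positions
      dv[t] = std::sqrt(d2[idx[t]]);
      if (!is_minority[idx[t]]) dirty[idx[t]] = true;
    }
    nbr_idx[mi] = iv;
    nbr_dist[mi] = dv;
  }

  std::vector<int> dirty_pos;
  for (int j = 0; j < n; ++j) if (dirty[j]) dirty_pos.push_back(j + 1);
  return List::create(
    _["minority_pos"] = IntegerVector(mino.begin(), mino.end()) + 1,
    _["neighbor_idx"] = nbr_idx,
    _["neighbor_dist"] = nbr_dist,
    _["dirty_pos"] = IntegerVector(dirty_pos.begin(), dirty_pos.end()));
}
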