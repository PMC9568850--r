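#include <Rcpp.h>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Rank-median filter over an arbitrary structuring element given as offset
// vectors (dx = column offsets, dy = row offsets). Borders are handled by
// edge replication (index clamping), so the colony rim is not pulled towards
// the dark background.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, IntegerVector dy,
                                IntegerVector dx) {
  const int nr = img.nrow(), nc = img.ncol(), k = dy.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m) {
        int ii = i + dy[m];
        int jj = j + dx[m];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        buf[m] = img(ii, jj);
      }
      int mid = k / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1,
                         buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask by breadth-first search.
// connectivity must be 4 or 8. Labels are 1..n in discovery order; 0 is
// background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int m = 0; m < nn; ++m) {
          int ii = p.first + dy8[m], jj = p.second + dx8[m];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
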