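#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window medians of a numeric vector: returns one median per
// contiguous window of length w (n - w + 1 values). Standard median:
// middle order statistic for odd w, mean of the two middle ones for even w.
// [[Rcpp::export(name = ".roll_median_cpp")]]
NumericVector roll_median_cpp(NumericVector x, int w) {
  int n = x.size();
  if (w < 1 || w > n) stop("window must be in [1, length(x)]");
  int nout = n - w + 1;
  NumericVector out(nout);
  std::vector<double> buf(w);
  int lo = (w - 1) / 2, hi = w / 2;  // equal when w is odd
  for (int i = 0; i < nout; ++i) {
    std::copy(x.begin() + i, x.begin() + i + w, buf.begin());
    std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
    double a = buf[lo];
    if (lo == hi) {
      out[i] = a;
    } else {
      std::nth_element(buf.begin() + lo + 1, buf.begin() + hi, buf.end());
      out[i] = 0.5 * (a + buf[hi]);
    }
  }
  return out;
}

// 8-connected labelling of a binary matrix (two-pass union-find).
// Returns an integer matrix of component labels, 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously scanned 8-neighbours (column-major scan)
      int neigh[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int cur = 0;
      for (int k = 0; k < 4; ++k) {
        int r = neigh[k][0], c = neigh[k][1];
        if (r < 0 || r >= nr || c < 0) continue;
        int l = lab(r, c);
        if (l > 0) {
          if (cur == 0) cur = l; else unite(cur, l);
        }
      }
      if (cur == 0) { cur = next++; parent.push_back(cur); }
      lab(i, j) = cur;
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++nlab;
        lab(i, j) = remap[r];
      }
  return lab;
}
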