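#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labeling by flood fill. `connectivity` is 4 or 8.
// Background (0) is labeled 0; components get 1, 2, ... in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1},
            dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second;
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return lab;
}

// Binary erosion/dilation with a 0/1 structuring element (odd side, origin
// at center). Pixels outside the raster count as background: erosion
// removes foreground touching the border, dilation never reads outside.
// [[Rcpp::export]]
IntegerMatrix cpp_morph(const IntegerMatrix& mask, const IntegerMatrix& elem,
                        bool erode) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int er = elem.nrow(), ec = elem.ncol();
  const int or_ = er / 2, oc = ec / 2;
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (erode) {
        if (mask(i, j) == 0) continue;
        int keep = 1;
        for (int b = 0; b < ec && keep; ++b) {
          for (int a = 0; a < er && keep; ++a) {
            if (elem(a, b) == 0) continue;
            int r2 = i + a - or_, c2 = j + b - oc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || mask(r2, c2) == 0)
              keep = 0;
          }
        }
        out(i, j) = keep;
      } else {
        if (mask(i, j) == 0) continue;
        for (int b = 0; b < ec; ++b) {
          for (int a = 0; a < er; ++a) {
            if (elem(a, b) == 0) continue;
            int r2 = i + a - or_, c2 = j + b - oc;
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) out(r2, c2) = 1;
          }
        }
      }
    }
  }
  return out;
}

// Square median filter on integer gray levels with edge replication.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int k) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = k / 2, win = k * k;
  IntegerMatrix out(nr, nc);
  std::vector<int> buf(win);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = 0;
      for (int b = -h; b <= h; ++b) {
        int c2 = j + b;
        if (c2 < 0) c2 = 0;
        if (c2 >= nc) c2 = nc - 1;
        for (int a = -h; a <= h; ++a) {
          int r2 = i + a;
          if (r2 < 0) r2 = 0;
          if (r2 >= nr) r2 = nr - 1;
          buf[n++] = img(r2, c2);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + win / 2, buf.begin() + n);
      out(i, j) = buf[win / 2];
    }
  }
  return out;
}

// Minimum squared Euclidean distance between two point sets (n x 2, x/y),
// returning c(d2, ia, ib) with 1-based indices of the closest pair.
// [[Rcpp::export]]
NumericVector cpp_closest_pair(const NumericMatrix& a, const NumericMatrix& b) {
  double best = R_PosInf;
  int ia = 0, ib = 0;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; ia = i + 1; ib = j + 1; }
    }
  }
  return NumericVector::create(best, ia, ib);
}
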