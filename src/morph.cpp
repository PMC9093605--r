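#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// clamp an index into [0, n-1] (edge replication)
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Square kernel median filter with edge-replicated padding.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0)
    stop("median filter kernel must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol();
  if (k == 1) return clone(img);
  int h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int dc = -h; dc <= h; ++dc) {
        int cc = clampi(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr)
          buf.push_back(img(clampi(r + dr, nr), cc));
      }
      size_t m = buf.size() / 2;  // k*k is odd
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(r, c) = buf[m];
    }
  }
  return out;
}

// 3x3 correlation with edge-replicated borders (used for Sobel gradients
// and 8-neighbour counting).
// [[Rcpp::export]]
NumericMatrix cpp_conv3(NumericMatrix img, NumericMatrix ker) {
  if (ker.nrow() != 3 || ker.ncol() != 3) stop("kernel must be 3x3");
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          s += ker(dr + 1, dc + 1) * img(clampi(r + dr, nr), clampi(c + dc, nc));
      out(r, c) = s;
    }
  }
  return out;
}

// Guo-Hall two-subiteration thinning, run to a fixed point. Input and
// output are 0/1 integer matrices; the result is an 8-connected set of
// one-pixel-wide curves with the same connectivity as the input.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  std::vector<std::pair<int,int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // 8-neighbourhood, clockwise from north; outside = background
          int p2 = (r > 0)                ? img(r - 1, c)     : 0;
          int p3 = (r > 0 && c < nc - 1)  ? img(r - 1, c + 1) : 0;
          int p4 = (c < nc - 1)           ? img(r,     c + 1) : 0;
          int p5 = (r < nr - 1 && c < nc - 1) ? img(r + 1, c + 1) : 0;
          int p6 = (r < nr - 1)           ? img(r + 1, c)     : 0;
          int p7 = (r < nr - 1 && c > 0)  ? img(r + 1, c - 1) : 0;
          int p8 = (c > 0)                ? img(r,     c - 1) : 0;
          int p9 = (r > 0 && c > 0)       ? img(r - 1, c - 1) : 0;
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                              : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            del.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < del.size(); ++i)
        img(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return img;
}

// Connected-component labelling by breadth-first search.
// connectivity is 4 (edge-sharing) or 8 (edge- or corner-sharing).
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  int nd = connectivity;
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int i = 0; i < nd; ++i) {
          int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
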