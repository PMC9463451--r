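#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Median of a scratch vector (modifies it). Standard middle/average-of-two rule.
static double median_inplace(std::vector<double> &v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (hi + v[n / 2 - 1]);
}

// 2-D median filter with (2*radius+1)^2 window, truncated at the borders.
// [[Rcpp::export(name = ".median_filter2d_cpp")]]
NumericMatrix median_filter2d_cpp(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(x(ii, jj));
      out(i, j) = median_inplace(buf);
    }
  }
  return out;
}

// Per-pixel median over a centered temporal window (truncated at the ends).
// cube: H x W x T array; returns background of the same shape.
// [[Rcpp::export(name = ".temporal_median_cpp")]]
NumericVector temporal_median_cpp(NumericVector cube, int half_window) {
  IntegerVector d = cube.attr("dim");
  const int H = d[0], W = d[1], T = d[2];
  NumericVector out(cube.size());
  out.attr("dim") = d;
  const R_xlen_t plane = (R_xlen_t)H * W;
  std::vector<double> buf;
  buf.reserve(2 * half_window + 1);
  for (R_xlen_t p = 0; p < plane; ++p) {
    for (int t = 0; t < T; ++t) {
      const int t0 = std::max(0, t - half_window), t1 = std::min(T - 1, t + half_window);
      buf.clear();
      for (int tt = t0; tt <= t1; ++tt) buf.push_back(cube[p + plane * tt]);
      out[p + plane * t] = median_inplace(buf);
    }
  }
  return out;
}

// Bilinear resampling: out(i,j) = img(i + dy(i,j), j + dx(i,j)), `fill`
// outside the frame. dx/dy may be scalar (global translation) or full fields.
// [[Rcpp::export(name = ".warp_bilinear_cpp")]]
NumericMatrix warp_bilinear_cpp(NumericMatrix img, NumericMatrix dy,
                                NumericMatrix dx, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const bool scalar = (dx.nrow() == 1 && dx.ncol() == 1);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double sy = i + (scalar ? dy(0, 0) : dy(i, j));
      const double sx = j + (scalar ? dx(0, 0) : dx(i, j));
      if (sy < 0 || sx < 0 || sy > nr - 1 || sx > nc - 1) {
        out(i, j) = fill;
        continue;
      }
      const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      const int y1 = std::min(y0 + 1, nr - 1), x1 = std::min(x0 + 1, nc - 1);
      const double fy = sy - y0, fx = sx - x0;
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Connected-component labeling of a binary mask (two-pass union-find).
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
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
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously visited neighbours in column-major order
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      const int nn = (connectivity == 8) ? 4 : 2;
      const int use[4] = {0, connectivity == 8 ? 1 : -1, 2, connectivity == 8 ? 3 : -1};
      for (int k = 0; k < 4; ++k) {
        if (use[k] < 0) continue;
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        const int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l; else unite(best, l);
          if (l < best) best = l;
        }
      }
      (void)nn;
      if (best == 0) {
        parent.push_back((int)parent.size());
        best = (int)parent.size() - 1;
      }
      lab(i, j) = best;
    }
  }
  // flatten and renumber 1..K
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        const int r = find(lab(i, j));
        if (!remap[r]) remap[r] = ++next;
        lab(i, j) = remap[r];
      }
  return lab;
}

// Zhang-Suen skeletonization of a binary mask.
// [[Rcpp::export(name = ".thin_skeleton_cpp")]]
IntegerMatrix thin_skeleton_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return m(i, j) ? 1 : 0;
  };
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          const int p[8] = {at(i - 1, j), at(i - 1, j + 1), at(i, j + 1),
                            at(i + 1, j + 1), at(i + 1, j), at(i + 1, j - 1),
                            at(i, j - 1), at(i - 1, j - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}
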