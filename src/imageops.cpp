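// Polygon scan-conversion and connected-component labelling.
//
// Rasterisation uses the pixel-centre rule in half-open image
// coordinates: mask pixel (u, v) at downsample d is labelled when the
// point ((u + 0.5) d, (v + 0.5) d) falls inside the polygon under the
// even-odd rule.  Polygons are painted in the order supplied, so the
// caller controls label priority by paint order.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix rasterise_polygons_cpp(List polys, IntegerVector labels,
                                     int width, int height, int downsample) {
  if (downsample < 1) stop("downsample must be >= 1");
  const int mw = (int)std::ceil((double)width / downsample);
  const int mh = (int)std::ceil((double)height / downsample);
  IntegerMatrix mask(mh, mw);
  const double d = (double)downsample;

  for (int pi = 0; pi < polys.size(); ++pi) {
    NumericMatrix P = polys[pi];
    const int nv = P.nrow();
    if (nv < 3) continue;
    const int lab = labels[pi];
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      ymin = std::min(ymin, P(i, 1));
      ymax = std::max(ymax, P(i, 1));
    }
    const int v0 = std::max(0, (int)std::floor(ymin / d - 0.5));
    const int v1 = std::min(mh - 1, (int)std::ceil(ymax / d - 0.5));
    std::vector<double> xs;
    for (int v = v0; v <= v1; ++v) {
      const double yc = (v + 0.5) * d;
      xs.clear();
      for (int i = 0; i < nv; ++i) {
        const int j = (i + 1) % nv;
        const double y1 = P(i, 1), y2 = P(j, 1);
        if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1)) {
          const double x1 = P(i, 0), x2 = P(j, 0);
          xs.push_back(x1 + (yc - y1) * (x2 - x1) / (y2 - y1));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        // pixels with centre x in [xs[k], xs[k+1])
        int u0 = (int)std::ceil(xs[k] / d - 0.5);
        int u1 = (int)std::floor(xs[k + 1] / d - 0.5);
        if ((u1 + 0.5) * d >= xs[k + 1]) --u1;  // strict upper bound
        u0 = std::max(u0, 0);
        u1 = std::min(u1, mw - 1);
        for (int u = u0; u <= u1; ++u)
          if ((u + 0.5) * d >= xs[k]) mask(v, u) = lab;
      }
    }
  }
  return mask;
}

// 8-connected components of a logical mask; labels 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int>> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.emplace_back(ni, nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
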