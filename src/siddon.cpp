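#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Parallel-beam geometry. A ray is indexed by (angle a, detector bin k):
//   origin  p0 = s * (cos a, sin a),  s = (k - (Y-1)/2) * bin_spacing
//   direction d = (-sin a, cos a)
// The image occupies [-w/2, w/2] x [-h/2, h/2] in mm (pixel_size * pixels),
// pixel (i, j) covering x in [j, j+1)*px - w/2, y in [i, i+1)*px - h/2.
// trace_ray emits (i, j, intersection length in mm) for every pixel the ray
// crosses, via plane-crossing (Siddon) traversal: exact lengths, no
// interpolation, so project / backproject / system-matrix share one
// discretization and are exact adjoints of one another.

struct Grid {
  int h, w;
  double px, xmin, ymin, xmax, ymax;
  Grid(int h_, int w_, double px_) : h(h_), w(w_), px(px_) {
    xmin = -0.5 * w * px; xmax = 0.5 * w * px;
    ymin = -0.5 * h * px; ymax = 0.5 * h * px;
  }
};

template <typename F>
static inline void trace_ray(const Grid& g, double cs, double sn, double s,
                             std::vector<double>& ts, F&& emit) {
  const double eps = 1e-12;
  const double inf = std::numeric_limits<double>::infinity();
  double p0x = s * cs, p0y = s * sn;
  double dx = -sn, dy = cs;
  double t0 = -inf, t1 = inf;
  if (std::fabs(dx) < eps) {
    if (p0x <= g.xmin || p0x >= g.xmax) return;
  } else {
    double ta = (g.xmin - p0x) / dx, tb = (g.xmax - p0x) / dx;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(dy) < eps) {
    if (p0y <= g.ymin || p0y >= g.ymax) return;
  } else {
    double ta = (g.ymin - p0y) / dy, tb = (g.ymax - p0y) / dy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (!(t1 > t0)) return;

  ts.clear();
  ts.push_back(t0); ts.push_back(t1);
  if (std::fabs(dx) >= eps)
    for (int m = 1; m < g.w; ++m) {
      double t = (g.xmin + m * g.px - p0x) / dx;
      if (t > t0 && t < t1) ts.push_back(t);
    }
  if (std::fabs(dy) >= eps)
    for (int m = 1; m < g.h; ++m) {
      double t = (g.ymin + m * g.px - p0y) / dy;
      if (t > t0 && t < t1) ts.push_back(t);
    }
  std::sort(ts.begin(), ts.end());
  for (size_t q = 0; q + 1 < ts.size(); ++q) {
    double len = ts[q + 1] - ts[q];
    if (len <= eps) continue;
    double tm = 0.5 * (ts[q] + ts[q + 1]);
    double xm = p0x + tm * dx, ym = p0y + tm * dy;
    int j = (int)std::floor((xm - g.xmin) / g.px);
    int i = (int)std::floor((ym - g.ymin) / g.px);
    if (i < 0 || i >= g.h || j < 0 || j >= g.w) continue;
    emit(i, j, len);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_project(NumericMatrix img, double pixel_size,
                          NumericVector angles, int nbins, double bin_spacing) {
  int h = img.nrow(), w = img.ncol(), X = angles.size();
  Grid g(h, w, pixel_size);
  NumericMatrix sino(X, nbins);
  std::vector<double> ts; ts.reserve(h + w + 4);
  for (int a = 0; a < X; ++a) {
    double cs = std::cos(angles[a]), sn = std::sin(angles[a]);
    for (int k = 0; k < nbins; ++k) {
      double s = (k - 0.5 * (nbins - 1)) * bin_spacing;
      double acc = 0.0;
      trace_ray(g, cs, sn, s, ts, [&](int i, int j, double len) {
        acc += len * img(i, j);
      });
      sino(a, k) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, int h, int w,
                              double pixel_size, NumericVector angles,
                              double bin_spacing) {
  int X = angles.size(), nbins = sino.ncol();
  Grid g(h, w, pixel_size);
  NumericMatrix img(h, w);
  std::vector<double> ts; ts.reserve(h + w + 4);
  for (int a = 0; a < X; ++a) {
    double cs = std::cos(angles[a]), sn = std::sin(angles[a]);
    for (int k = 0; k < nbins; ++k) {
      double s = (k - 0.5 * (nbins - 1)) * bin_spacing;
      double v = sino(a, k);
      if (v == 0.0) continue;
      trace_ray(g, cs, sn, s, ts, [&](int i, int j, double len) {
        img(i, j) += len * v;
      });
    }
  }
  return img;
}

// Triplets for the explicit sparse system matrix. Row order is angle-major
// then bin (row = a * nbins + k); column order is row-major pixels
// (col = i * w + j). Indices returned 1-based for Matrix::sparseMatrix.
// [[Rcpp::export]]
List cpp_system_matrix(int h, int w, double pixel_size, NumericVector angles,
                       int nbins, double bin_spacing) {
  int X = angles.size();
  Grid g(h, w, pixel_size);
  std::vector<int> ri, ci;
  std::vector<double> vals;
  std::vector<double> ts; ts.reserve(h + w + 4);
  for (int a = 0; a < X; ++a) {
    double cs = std::cos(angles[a]), sn = std::sin(angles[a]);
    for (int k = 0; k < nbins; ++k) {
      double s = (k - 0.5 * (nbins - 1)) * bin_spacing;
      int row = a * nbins + k;
      trace_ray(g, cs, sn, s, ts, [&](int i, int j, double len) {
        ri.push_back(row + 1);
        ci.push_back(i * w + j + 1);
        vals.push_back(len);
      });
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(vals));
}
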