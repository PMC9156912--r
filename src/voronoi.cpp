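#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sutherland-Hodgman clip of a (possibly non-convex) polygon against the
// half-plane nx*x + ny*y <= c. Area stays exact for half-plane clips.
static void clip_half(std::vector<double>& xs, std::vector<double>& ys,
                      double nx, double ny, double c) {
  int n = (int)xs.size();
  if (n == 0) return;
  std::vector<double> ox, oy;
  ox.reserve(n + 4); oy.reserve(n + 4);
  const double eps = 1e-12;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double dj = nx * xs[j] + ny * ys[j] - c;
    double di = nx * xs[i] + ny * ys[i] - c;
    bool inj = dj <= eps, ini = di <= eps;
    if (inj != ini) {
      double t = dj / (dj - di);
      ox.push_back(xs[j] + t * (xs[i] - xs[j]));
      oy.push_back(ys[j] + t * (ys[i] - ys[j]));
    }
    if (ini) { ox.push_back(xs[i]); oy.push_back(ys[i]); }
  }
  xs.swap(ox); ys.swap(oy);
}

static double shoelace(const std::vector<double>& xs,
                       const std::vector<double>& ys) {
  int n = (int)xs.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += xs[j] * ys[i] - xs[i] * ys[j];
  return std::fabs(a) / 2.0;
}

// Voronoi cells of `pos` clipped to `poly`; returns exact cell areas and,
// if `rect` = (xmin, xmax, ymin, ymax) is non-empty, the exact area of each
// cell intersected with the rectangle.
// [[Rcpp::export]]
List cpp_voronoi_cells(NumericMatrix pos, NumericMatrix poly,
                       NumericVector rect) {
  int n = pos.nrow(), m = poly.nrow();
  bool with_rect = rect.size() == 4;
  NumericVector cell_area(n), rect_area(n);

  std::vector<double> px(m), py(m);
  for (int j = 0; j < m; ++j) { px[j] = poly(j, 0); py[j] = poly(j, 1); }

  for (int i = 0; i < n; ++i) {
    std::vector<double> xs(px), ys(py);
    double xi = pos(i, 0), yi = pos(i, 1);
    for (int j = 0; j < n && !xs.empty(); ++j) {
      if (j == i) continue;
      double nx = pos(j, 0) - xi, ny = pos(j, 1) - yi;
      double c = 0.5 * (pos(j, 0) * pos(j, 0) + pos(j, 1) * pos(j, 1)
                        - xi * xi - yi * yi);
      clip_half(xs, ys, nx, ny, c);
    }
    cell_area[i] = shoelace(xs, ys);
    if (with_rect) {
      clip_half(xs, ys,  1.0, 0.0,  rect[1]);
      clip_half(xs, ys, -1.0, 0.0, -rect[0]);
      clip_half(xs, ys,  0.0, 1.0,  rect[3]);
      clip_half(xs, ys,  0.0, -1.0, -rect[2]);
      rect_area[i] = shoelace(xs, ys);
    }
  }
  return List::create(_["cell_area"] = cell_area, _["rect_area"] = rect_area);
}

// Frame-averaged sum of unit-integral isotropic Gaussians
// (1/(pi a^2)) exp(-|r - r_i|^2 / a^2) evaluated on the xg x yg node grid.
// `pts` pools the agent positions of all frames; nframes divides the sum.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_field(NumericMatrix pts, int nframes,
                                 NumericVector xg, NumericVector yg, double a) {
  int nx = xg.size(), ny = yg.size(), np = pts.nrow();
  NumericMatrix out(nx, ny);
  double norm = 1.0 / (M_PI * a * a) / (double)nframes;
  double ia2 = 1.0 / (a * a);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    for (int iy = 0; iy < ny; ++iy) {
      double dy = yg[iy] - y, dy2 = dy * dy;
      for (int ix = 0; ix < nx; ++ix) {
        double dx = xg[ix] - x;
        out(ix, iy) += norm * std::exp(-(dx * dx + dy2) * ia2);
      }
    }
  }
  return out;
}
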