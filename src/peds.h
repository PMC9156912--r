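#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>

// distance from (px,py) to segment (x1,y1)-(x2,y2)
inline double seg_dist(double px, double py,
                       double x1, double y1, double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = (L2 > 0.0) ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

inline double walls_dist(double px, double py, const Rcpp::NumericMatrix& W) {
  double d = R_PosInf;
  for (int k = 0; k < W.nrow(); ++k) {
    double dk = seg_dist(px, py, W(k, 0), W(k, 1), W(k, 2), W(k, 3));
    if (dk < d) d = dk;
  }
  return d;
}

// even-odd point-in-polygon with an on-boundary tolerance
inline bool point_in_poly(double px, double py,
                          const Rcpp::NumericMatrix& poly, double tol) {
  int m = poly.nrow();
  bool inside = false;
  for (int j = 0, k = m - 1; j < m; k = j++) {
    double xj = poly(j, 0), yj = poly(j, 1);
    double xk = poly(k, 0), yk = poly(k, 1);
    if (seg_dist(px, py, xj, yj, xk, yk) <= tol) return true;
    if (((yj > py) != (yk > py)) &&
        (px < (xk - xj) * (py - yj) / (yk - yj) + xj))
      inside = !inside;
  }
  return inside;
}

// do the segments (p1-p2) and (q1-q2) intersect (touching counts)?
inline bool segs_intersect(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  auto orient = [](double ax, double ay, double bx, double by,
                   double cx, double cy) {
    double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (v > 1e-14) return 1;
    if (v < -1e-14) return -1;
    return 0;
  };
  int o1 = orient(p1x, p1y, p2x, p2y, q1x, q1y);
  int o2 = orient(p1x, p1y, p2x, p2y, q2x, q2y);
  int o3 = orient(q1x, q1y, q2x, q2y, p1x, p1y);
  int o4 = orient(q1x, q1y, q2x, q2y, p2x, p2y);
  if (o1 != o2 && o3 != o4) return true;
  auto on_seg = [](double ax, double ay, double bx, double by,
                   double cx, double cy) {
    return cx >= std::fmin(ax, bx) - 1e-14 && cx <= std::fmax(ax, bx) + 1e-14 &&
           cy >= std::fmin(ay, by) - 1e-14 && cy <= std::fmax(ay, by) + 1e-14;
  };
  if (o1 == 0 && on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) return true;
  if (o2 == 0 && on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) return true;
  if (o3 == 0 && on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) return true;
  if (o4 == 0 && on_seg(q1x, q1y, q2x, q2y, p2x, p2y)) return true;
  return false;
}

inline bool crosses_walls(double x1, double y1, double x2, double y2,
                          const Rcpp::NumericMatrix& W) {
  for (int k = 0; k < W.nrow(); ++k)
    if (segs_intersect(x1, y1, x2, y2, W(k, 0), W(k, 1), W(k, 2), W(k, 3)))
      return true;
  return false;
}

// distance along the ray p + t*e (t >= 0) to the first wall segment hit;
// +Inf when the ray escapes. Rays parallel to a segment do not hit it, so
// sliding along a wall is not speed-limited by it.
inline double ray_walls(double px, double py, double ex, double ey,
                        const Rcpp::NumericMatrix& W) {
  double best = R_PosInf;
  for (int k = 0; k < W.nrow(); ++k) {
    double ax = W(k, 0), ay = W(k, 1);
    double dx = W(k, 2) - ax, dy = W(k, 3) - ay;
    double den = ex * dy - ey * dx;
    if (std::fabs(den) < 1e-14) continue;
    double t = ((ax - px) * dy - (ay - py) * dx) / den;
    double u = ((ax - px) * ey - (ay - py) * ex) / den;
    if (t >= 0.0 && u >= -1e-12 && u <= 1.0 + 1e-12 && t < best) best = t;
  }
  return best;
}

// bilinear interpolation of a nodal vector field, skipping invalid corners.
// grids are column-major nx x ny, node (ix,iy) at index ix + iy*nx,
// node coordinates x0 + ix*h, y0 + iy*h.
struct DirField {
  double x0, y0, h;
  int nx, ny;
  const double* gx;
  const double* gy;
  const int* valid;

  // returns 0 ok, 1 no valid corner, 2 zero gradient; on ok ex,ey = -grad/|grad|
  int query(double x, double y, double& ex, double& ey) const {
    double fx = (x - x0) / h, fy = (y - y0) / h;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
    if (ix < 0) ix = 0; if (ix > nx - 2) ix = nx - 2;
    if (iy < 0) iy = 0; if (iy > ny - 2) iy = ny - 2;
    double tx = fx - ix, ty = fy - iy;
    if (tx < 0.0) tx = 0.0; if (tx > 1.0) tx = 1.0;
    if (ty < 0.0) ty = 0.0; if (ty > 1.0) ty = 1.0;
    int idx[4] = { ix + iy * nx, ix + 1 + iy * nx,
                   ix + (iy + 1) * nx, ix + 1 + (iy + 1) * nx };
    double w[4] = { (1 - tx) * (1 - ty), tx * (1 - ty),
                    (1 - tx) * ty, tx * ty };
    double sw = 0.0, sx = 0.0, sy = 0.0;
    for (int k = 0; k < 4; ++k) {
      if (valid[idx[k]]) {
        sw += w[k];
        sx += w[k] * gx[idx[k]];
        sy += w[k] * gy[idx[k]];
      }
    }
    if (sw < 1e-12) return 1;
    sx /= sw; sy /= sw;
    double n = std::sqrt(sx * sx + sy * sy);
    if (n < 1e-12) return 2;
    ex = -sx / n; ey = -sy / n;
    return 0;
  }
};
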