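#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// quadratic upwind update from the axis minima a, b with local cost fh = F*h
static inline double eikonal_update(double a, double b, double fh) {
  if (!R_FINITE(a) && !R_FINITE(b)) return R_PosInf;
  if (!R_FINITE(a)) return b + fh;
  if (!R_FINITE(b)) return a + fh;
  double lo = (a < b) ? a : b, hi = (a < b) ? b : a;
  if (hi - lo >= fh) return lo + fh;  // causality: one-sided update
  double d = a - b;
  return 0.5 * (a + b + std::sqrt(2.0 * fh * fh - d * d));
}

// First-order fast marching for |grad c| = F on a regular nx x ny grid
// (column-major, node ix + iy*nx). F is the slowness, `walkable` masks the
// domain, `targets` are 0-based node indices where c = 0.
// Non-walkable and unreachable nodes come back as +Inf.
// [[Rcpp::export]]
NumericVector cpp_fast_march(int nx, int ny, double h,
                             NumericVector F, LogicalVector walkable,
                             IntegerVector targets) {
  int n = nx * ny;
  NumericVector cost(n, R_PosInf);
  std::vector<char> state(n, 0);  // 0 far, 1 trial, 2 accepted

  typedef std::pair<double, int> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > heap;

  for (int k = 0; k < targets.size(); ++k) {
    int idx = targets[k];
    if (idx < 0 || idx >= n || !walkable[idx])
      stop("target cell outside the walkable domain");
    cost[idx] = 0.0;
    state[idx] = 1;
    heap.push(QN(0.0, idx));
  }

  while (!heap.empty()) {
    QN top = heap.top();
    heap.pop();
    int idx = top.second;
    if (state[idx] == 2) continue;
    if (top.first > cost[idx] + 1e-15) continue;  // stale entry
    state[idx] = 2;

    int ix = idx % nx, iy = idx / nx;
    const int dxs[4] = { -1, 1, 0, 0 };
    const int dys[4] = { 0, 0, -1, 1 };
    for (int d = 0; d < 4; ++d) {
      int jx = ix + dxs[d], jy = iy + dys[d];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) continue;
      int j = jx + jy * nx;
      if (!walkable[j] || state[j] == 2) continue;

      // axis minima over accepted neighbours of j
      double a = R_PosInf, b = R_PosInf;
      if (jx > 0      && state[j - 1]  == 2) a = cost[j - 1];
      if (jx < nx - 1 && state[j + 1]  == 2 && cost[j + 1] < a) a = cost[j + 1];
      if (jy > 0      && state[j - nx] == 2) b = cost[j - nx];
      if (jy < ny - 1 && state[j + nx] == 2 && cost[j + nx] < b) b = cost[j + nx];

      double cand = eikonal_update(a, b, F[j] * h);
      if (cand < cost[j]) {
        cost[j] = cand;
        state[j] = 1;
        heap.push(QN(cand, j));
      }
    }
  }
  return cost;
}
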