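#include "peds.h"
using namespace Rcpp;

// headway spacing per agent: minimum effective headway over the set of
// agents in the forward half-plane of the movement direction whose
// perpendicular offset from the movement line is below one body diameter l.
// The effective headway is the free walking distance along the movement
// direction until contact, expressed as an equivalent centre distance:
// s_eff = e.r - sqrt(l^2 - perp^2) + l; for an agent dead ahead this is the
// centre-to-centre distance. Ties resolve to the lowest index.
static inline void headway_min(int i, int n,
                               const double* x, const double* y,
                               const char* live,
                               double exi, double eyi, double l,
                               double& smin, int& jmin) {
  smin = R_PosInf; jmin = -1;
  double xi = x[i], yi = y[i];
  for (int j = 0; j < n; ++j) {
    if (j == i || !live[j]) continue;
    double rx = x[j] - xi, ry = y[j] - yi;
    double fdot = exi * rx + eyi * ry;
    if (fdot < 0.0) continue;                  // behind the movement line
    double perp = std::fabs(exi * ry - eyi * rx);
    if (perp >= l) continue;                   // outside the lateral band
    double s = fdot - std::sqrt(l * l - perp * perp) + l;
    if (s < smin) { smin = s; jmin = j; }
  }
}

// Exported headway query: minimum *centre-to-centre* distance over the
// headway set (forward half-plane, perpendicular offset < l), as used by
// the measurement side; ties resolve to the lowest index.
// [[Rcpp::export]]
List cpp_headway(NumericMatrix pos, NumericMatrix dirs, double l) {
  int n = pos.nrow();
  NumericVector s(n, R_PosInf);
  IntegerVector jmin(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    double xi = pos(i, 0), yi = pos(i, 1);
    double exi = dirs(i, 0), eyi = dirs(i, 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rx = pos(j, 0) - xi, ry = pos(j, 1) - yi;
      double fdot = exi * rx + eyi * ry;
      if (fdot < 0.0) continue;
      double perp = std::fabs(exi * ry - eyi * rx);
      if (perp >= l) continue;
      double d = std::sqrt(rx * rx + ry * ry);
      if (d < s[i]) { s[i] = d; jmin[i] = j + 1; }
    }
  }
  return List::create(_["spacing"] = s, _["neighbor"] = jmin);
}

// [[Rcpp::export]]
List cpp_dir_at(NumericMatrix pts, NumericVector grid,
                NumericVector gx, NumericVector gy, IntegerVector gvalid) {
  DirField f;
  f.x0 = grid[0]; f.y0 = grid[1]; f.h = grid[2];
  f.nx = (int)grid[3]; f.ny = (int)grid[4];
  f.gx = gx.begin(); f.gy = gy.begin(); f.valid = gvalid.begin();
  int n = pts.nrow();
  NumericMatrix dir(n, 2);
  IntegerVector code(n);
  for (int i = 0; i < n; ++i) {
    double ex = NA_REAL, ey = NA_REAL;
    code[i] = f.query(pts(i, 0), pts(i, 1), ex, ey);
    dir(i, 0) = ex; dir(i, 1) = ey;
  }
  return List::create(_["dir"] = dir, _["code"] = code);
}

// Synchronous update of the collision-free speed model with floor-field
// navigation, directional noise, an overlap guard that freezes violators,
// and exit bookkeeping at the y = 0 line. Walls act through the floor field;
// the guard only forbids penetrating a containment segment. Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericVector grid,
                  NumericVector gx, NumericVector gy, IntegerVector gvalid,
                  NumericMatrix containment,
                  double exit_half, double exit_depth,
                  double v0, double l, double T, double noise_sd, double dt,
                  int max_steps, int stride, bool remove_at_exit) {
  int n = pos0.nrow();
  DirField f;
  f.x0 = grid[0]; f.y0 = grid[1]; f.h = grid[2];
  f.nx = (int)grid[3]; f.ny = (int)grid[4];
  f.gx = gx.begin(); f.gy = gy.begin(); f.valid = gvalid.begin();

  std::vector<double> x(n), y(n), ex(n), ey(n);
  std::vector<char> live(n, 1), exited(n, 0);
  NumericVector exit_time(n, NA_REAL);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }

  int nrec = max_steps / stride + 1;
  NumericVector rec((R_xlen_t)nrec * n * 2, NA_REAL);
  for (int i = 0; i < n; ++i) { rec[i] = x[i]; rec[n + i] = y[i]; }

  int n_exited = 0, frames = 1, fallbacks = 0;
  long freeze_events = 0;
  double drop_y = -exit_depth + l / 2.0;     // open end of the passage
  double l_eps = l - 1e-9;
  double l2 = l_eps * l_eps;
  double t = 0.0;
  int step = 0;

  for (step = 1; step <= max_steps; ++step) {
    // desired directions (floor field + noise)
    for (int i = 0; i < n; ++i) {
      if (!live[i]) continue;
      double e0x, e0y;
      if (y[i] <= 0.0) {                     // inside the downstream passage
        e0x = 0.0; e0y = -1.0;
      } else if (f.query(x[i], y[i], e0x, e0y) != 0) {
        // flat spot or masked corners: head for the exit centre
        double nx = -x[i], ny = -y[i], nn = std::sqrt(nx * nx + ny * ny);
        if (nn < 1e-12) { e0x = 0.0; e0y = -1.0; }
        else { e0x = nx / nn; e0y = ny / nn; }
        ++fallbacks;
      }
      if (noise_sd > 0.0) {
        double vx, vy, nn;
        do {
          vx = e0x + norm_rand() * noise_sd;
          vy = e0y + norm_rand() * noise_sd;
          nn = std::sqrt(vx * vx + vy * vy);
        } while (nn < 1e-12);
        ex[i] = vx / nn; ey[i] = vy / nn;
      } else {
        ex[i] = e0x; ey[i] = e0y;
      }
    }

    // sequential position update in ascending id: spacing, speed and the
    // candidate are evaluated against current positions (walls ahead limit
    // speed like a neighbour at ray distance s_w with body clearance l/2);
    // a candidate that would overlap another agent or penetrate a wall is
    // rejected -- the agent keeps its position with velocity 0 for this step
    for (int i = 0; i < n; ++i) {
      if (!live[i]) continue;
      double s; int jm;
      headway_min(i, n, x.data(), y.data(), live.data(), ex[i], ey[i], l, s, jm);
      double V;
      if (!R_FINITE(s)) V = v0;
      else if (T > 0.0) {
        V = (s - l) / T;
        if (V < 0.0) V = 0.0;
        if (V > v0) V = v0;
      } else V = (s > l) ? v0 : 0.0;         // T -> 0: pure volume exclusion
      double sw = ray_walls(x[i], y[i], ex[i], ey[i], containment);
      if (R_FINITE(sw)) {
        double Vw;
        if (T > 0.0) {
          Vw = (sw - l / 2.0) / T;
          if (Vw < 0.0) Vw = 0.0;
        } else Vw = (sw > l / 2.0) ? v0 : 0.0;
        if (Vw < V) V = Vw;
      }
      if (V <= 0.0) continue;
      double cxi = x[i] + V * ex[i] * dt;
      double cyi = y[i] + V * ey[i] * dt;

      bool bad = crosses_walls(x[i], y[i], cxi, cyi, containment);
      if (!bad) {
        for (int j = 0; j < n; ++j) {
          if (j == i || !live[j]) continue;
          double dx = cxi - x[j], dy = cyi - y[j];
          if (dx * dx + dy * dy < l2) { bad = true; break; }
        }
      }
      if (bad) { ++freeze_events; continue; }

      if (!exited[i] && y[i] > 0.0 && cyi <= 0.0) {
        double frac = y[i] / (y[i] - cyi);
        double xs = x[i] + frac * (cxi - x[i]);
        if (std::fabs(xs) <= exit_half + 1e-9) {
          exited[i] = 1;
          exit_time[i] = t + frac * dt;
          ++n_exited;
          if (remove_at_exit) { live[i] = 0; continue; }
        } else {                              // grazing the lower wall line
          continue;
        }
      }
      x[i] = cxi; y[i] = cyi;
      if (y[i] <= drop_y) live[i] = 0;
    }
    t += dt;

    if (step % stride == 0) {
      int fidx = step / stride;
      R_xlen_t off = (R_xlen_t)fidx * n * 2;
      for (int i = 0; i < n; ++i) {
        if (live[i]) { rec[off + i] = x[i]; rec[off + n + i] = y[i]; }
      }
      frames = fidx + 1;
    }
    if (n_exited == n) break;
  }

  return List::create(
    _["pos"] = rec, _["n_frames"] = frames,
    _["exit_time"] = exit_time, _["n_exited"] = n_exited,
    _["fallbacks"] = fallbacks, _["freeze_events"] = (double)freeze_events,
    _["steps_run"] = (step > max_steps) ? max_steps : step);
}

// Sequential hard-core placement: uniform draws over the rectangle rejected
// until inside the walkable polygon, all pairwise distances >= l and wall
// clearance >= l/2. Restarts the whole configuration when an agent exhausts
// its attempt budget.
// [[Rcpp::export]]
NumericMatrix cpp_place_agents(int n, double xmin, double xmax,
                               double ymin, double ymax,
                               NumericMatrix walls, NumericMatrix poly,
                               double l, int attempts, int restarts) {
  NumericMatrix out(n, 2);
  double l2 = l * l, wmin = l / 2.0;
  for (int r = 0; r < restarts; ++r) {
    int placed = 0;
    for (; placed < n; ++placed) {
      bool ok = false;
      for (int a = 0; a < attempts && !ok; ++a) {
        double px = xmin + unif_rand() * (xmax - xmin);
        double py = ymin + unif_rand() * (ymax - ymin);
        if (py <= 0.0 || !point_in_poly(px, py, poly, 0.0)) continue;
        if (walls_dist(px, py, walls) < wmin) continue;
        ok = true;
        for (int j = 0; j < placed; ++j) {
          double dx = px - out(j, 0), dy = py - out(j, 1);
          if (dx * dx + dy * dy < l2) { ok = false; break; }
        }
        if (ok) { out(placed, 0) = px; out(placed, 1) = py; }
      }
      if (!ok) break;
    }
    if (placed == n) return out;
  }
  stop("agent placement failed: could not fit %d discs of diameter %.3g into "
       "[%.3g, %.3g] x [%.3g, %.3g] with l/2 wall clearance (attempt budget "
       "%d x %d exhausted)", n, l, xmin, xmax, ymin, ymax, attempts, restarts);
  return out;  // not reached
}
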