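#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Blind/myopic-ant walk on a periodic obstacle lattice, recorded once per
// frame. Coordinates are unwrapped lattice indices (0-based); occupancy is
// checked on the wrapped position. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_obstructed_walk(const LogicalMatrix& occ, int start_i, int start_j,
                                  int n_frames, int steps_per_frame, bool myopic) {
  const int side = occ.nrow();
  IntegerMatrix out(n_frames + 1, 2);
  long ci = start_i, cj = start_j; // unwrapped, 0-based
  out(0, 0) = (int)ci;
  out(0, 1) = (int)cj;
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  for (int f = 1; f <= n_frames; ++f) {
    for (int s = 0; s < steps_per_frame; ++s) {
      if (!myopic) {
        int d = (int)(unif_rand() * 4.0);
        if (d > 3) d = 3;
        long ni = ci + di[d], nj = cj + dj[d];
        int wi = (int)(((ni % side) + side) % side);
        int wj = (int)(((nj % side) + side) % side);
        if (!occ(wi, wj)) { ci = ni; cj = nj; }
      } else {
        int vac[4], nv = 0;
        for (int d = 0; d < 4; ++d) {
          long ni = ci + di[d], nj = cj + dj[d];
          int wi = (int)(((ni % side) + side) % side);
          int wj = (int)(((nj % side) + side) % side);
          if (!occ(wi, wj)) vac[nv++] = d;
        }
        if (nv > 0) {
          int k = (int)(unif_rand() * nv);
          if (k >= nv) k = nv - 1;
          ci += di[vac[k]];
          cj += dj[vac[k]];
        }
      }
    }
    out(f, 0) = (int)ci;
    out(f, 1) = (int)cj;
  }
  return out;
}

// Does the vacant phase contain a 4-connected path from the top row (i = 0)
// to the bottom row (i = side-1)? Non-periodic spanning check.
// [[Rcpp::export]]
bool cpp_spans(const LogicalVector& occ, int side) {
  std::vector<char> seen((size_t)side * side, 0);
  std::queue<int> q;
  for (int j = 0; j < side; ++j) {
    int idx = j * side; // column-major, row 0
    if (!occ[idx]) { seen[idx] = 1; q.push(idx); }
  }
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % side, j = idx / side;
    if (i == side - 1) return true;
    for (int d = 0; d < 4; ++d) {
      int ni = i + di[d], nj = j + dj[d];
      if (ni < 0 || ni >= side || nj < 0 || nj >= side) continue;
      int nidx = nj * side + ni;
      if (!occ[nidx] && !seen[nidx]) { seen[nidx] = 1; q.push(nidx); }
    }
  }
  return false;
}

// 4-connected labelling of TRUE pixels; 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_label4(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int d = 0; d < 4; ++d) {
          int ni = p.first + di[d], nj = p.second + dj[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// Fold a proposed 1D move into the fence grid of pitch L: every grid line the
// segment crosses is tested independently in crossing order; an accepted
// crossing moves the walker into the next cell, a rejected one reflects the
// remaining displacement off the fence. `cell` is updated in place.
static double fence_fold_1d(double pos, double prop, double L, double p, long* cell) {
  for (int guard = 0; guard < 100000; ++guard) {
    double lo = (*cell) * L, hi = lo + L;
    if (prop >= lo && prop <= hi) return prop;
    double b = (prop > hi) ? hi : lo;
    if (unif_rand() < p) {
      *cell += (prop > hi) ? 1 : -1;
    } else {
      prop = 2.0 * b - prop;
    }
  }
  return prop; // unreachable at physical step sizes
}

// Hop diffusion across a square grid of permeable fences (pitch L).
// Gaussian steps, sd = sigma per axis. Start inside cell (0,0).
// [[Rcpp::export]]
NumericMatrix cpp_fenced_walk(int n_steps, double L, double p, double sigma,
                              double x0, double y0) {
  NumericMatrix out(n_steps + 1, 2);
  double x = x0, y = y0;
  long cx = (long)std::floor(x / L), cy = (long)std::floor(y / L);
  out(0, 0) = x; out(0, 1) = y;
  for (int s = 1; s <= n_steps; ++s) {
    x = fence_fold_1d(x, x + norm_rand() * sigma, L, p, &cx);
    y = fence_fold_1d(y, y + norm_rand() * sigma, L, p, &cy);
    out(s, 0) = x; out(s, 1) = y;
  }
  return out;
}

static int find_rect(const NumericMatrix& rects, double x, double y, double eps) {
  for (int r = 0; r < rects.nrow(); ++r) {
    if (x >= rects(r, 0) - eps && x <= rects(r, 1) + eps &&
        y >= rects(r, 2) - eps && y <= rects(r, 3) + eps) return r;
  }
  return -1;
}

// Gaussian walk confined by the walls of an axis-aligned rectangle tiling.
// Interior walls are permeable fences (acceptance probability p per
// crossing, reflection on rejection); the outer region boundary always
// reflects. rects columns: xmin, xmax, ymin, ymax.
// [[Rcpp::export]]
NumericMatrix cpp_mesh_confined_walk(const NumericMatrix& rects, int start_rect,
                                     double x0, double y0, double p, double sigma,
                                     int n_steps, NumericVector region) {
  NumericMatrix out(n_steps + 1, 2);
  double cx = x0, cy = y0;
  int rc = start_rect;
  const double eps = 1e-9;
  out(0, 0) = cx; out(0, 1) = cy;
  for (int s = 1; s <= n_steps; ++s) {
    double tx = cx + norm_rand() * sigma;
    double ty = cy + norm_rand() * sigma;
    for (int guard = 0; guard < 100000; ++guard) {
      double xmin = rects(rc, 0), xmax = rects(rc, 1);
      double ymin = rects(rc, 2), ymax = rects(rc, 3);
      if (tx >= xmin && tx <= xmax && ty >= ymin && ty <= ymax) break;
      // parametric first crossing along (cx,cy) -> (tx,ty)
      double best_t = 2.0; int axis = -1; double wall = 0.0; int dir = 0;
      if (tx > xmax) { double t = (xmax - cx) / (tx - cx); if (t < best_t) { best_t = t; axis = 0; wall = xmax; dir = 1; } }
      if (tx < xmin) { double t = (xmin - cx) / (tx - cx); if (t < best_t) { best_t = t; axis = 0; wall = xmin; dir = -1; } }
      if (ty > ymax) { double t = (ymax - cy) / (ty - cy); if (t < best_t) { best_t = t; axis = 1; wall = ymax; dir = 1; } }
      if (ty < ymin) { double t = (ymin - cy) / (ty - cy); if (t < best_t) { best_t = t; axis = 1; wall = ymin; dir = -1; } }
      if (axis < 0) break;
      double qx = cx + best_t * (tx - cx);
      double qy = cy + best_t * (ty - cy);
      bool outer = (axis == 0)
        ? (std::fabs(wall - region[0]) < eps || std::fabs(wall - region[1]) < eps)
        : (std::fabs(wall - region[2]) < eps || std::fabs(wall - region[3]) < eps);
      if (!outer && unif_rand() < p) {
        // hop: move just across the wall and relocate compartment
        double px = qx, py = qy;
        if (axis == 0) px = wall + dir * eps; else py = wall + dir * eps;
        int nr = find_rect(rects, px, py, eps / 2);
        if (nr < 0) { // numerical corner case: treat as reflection
          if (axis == 0) tx = 2.0 * wall - tx; else ty = 2.0 * wall - ty;
          cx = qx - ((axis == 0) ? dir * eps : 0);
          cy = qy - ((axis == 1) ? dir * eps : 0);
        } else {
          rc = nr;
          cx = px; cy = py;
        }
      } else {
        if (axis == 0) { tx = 2.0 * wall - tx; cx = wall - dir * eps; cy = qy; }
        else           { ty = 2.0 * wall - ty; cy = wall - dir * eps; cx = qx; }
      }
    }
    cx = tx; cy = ty;
    out(s, 0) = cx; out(s, 1) = cy;
  }
  return out;
}
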