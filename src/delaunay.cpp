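#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation of a 2-D point set.
// Points are inserted in the order given; callers are expected to break
// exact cocircularity (e.g. lattice input) with a tiny deterministic jitter.

namespace {

struct Tri {
  int a, b, c;       // vertex indices (0-based; negative never used)
  double cx, cy, r2; // circumcircle
  bool alive;
};

inline void circumcircle(const std::vector<double>& x,
                         const std::vector<double>& y,
                         Tri& t) {
  double ax = x[t.a], ay = y[t.a];
  double bx = x[t.b], by = y[t.b];
  double cx = x[t.c], cy = y[t.c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) { // degenerate: huge circle so it always dies
    t.cx = 0.0; t.cy = 0.0; t.r2 = 1e300;
    return;
  }
  double a2 = ax * ax + ay * ay;
  double b2 = bx * bx + by * by;
  double c2 = cx * cx + cy * cy;
  t.cx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
}

} // namespace

// [[Rcpp::export(name = ".cpp_delaunay")]]
IntegerMatrix cpp_delaunay(NumericVector px, NumericVector py) {
  int n = px.size();
  if (n < 3) stop("need at least 3 points");

  std::vector<double> x(px.begin(), px.end());
  std::vector<double> y(py.begin(), py.end());

  // super-triangle enclosing everything
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  x.push_back(midx - 20.0 * dmax); y.push_back(midy - 10.0 * dmax);
  x.push_back(midx + 20.0 * dmax); y.push_back(midy - 10.0 * dmax);
  x.push_back(midx);               y.push_back(midy + 20.0 * dmax);

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  Tri super = {n, n + 1, n + 2, 0, 0, 0, true};
  circumcircle(x, y, super);
  tris.push_back(super);

  std::vector<int> bad;
  std::vector<std::pair<int, int> > edges;

  for (int ip = 0; ip < n; ++ip) {
    double pxi = x[ip], pyi = y[ip];
    bad.clear();
    edges.clear();
    for (int it = 0; it < (int)tris.size(); ++it) {
      if (!tris[it].alive) continue;
      double dx = pxi - tris[it].cx, dy = pyi - tris[it].cy;
      if (dx * dx + dy * dy <= tris[it].r2 * (1.0 + 1e-12)) bad.push_back(it);
    }
    // boundary edges of the cavity = edges appearing exactly once
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& t = tris[bad[k]];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int j = 0; j < 3; ++j) {
        int u = e[j][0], v = e[j][1];
        bool dup = false;
        for (size_t m = 0; m < edges.size(); ++m) {
          if ((edges[m].first == v && edges[m].second == u) ||
              (edges[m].first == u && edges[m].second == v)) {
            edges.erase(edges.begin() + m);
            dup = true;
            break;
          }
        }
        if (!dup) edges.push_back(std::make_pair(u, v));
      }
      tris[bad[k]].alive = false;
    }
    for (size_t m = 0; m < edges.size(); ++m) {
      Tri t = {edges[m].first, edges[m].second, ip, 0, 0, 0, true};
      circumcircle(x, y, t);
      tris.push_back(t);
    }
  }

  int count = 0;
  for (size_t it = 0; it < tris.size(); ++it)
    if (tris[it].alive && tris[it].a < n && tris[it].b < n && tris[it].c < n)
      ++count;

  IntegerMatrix out(count, 3);
  int row = 0;
  for (size_t it = 0; it < tris.size(); ++it) {
    const Tri& t = tris[it];
    if (!t.alive || t.a >= n || t.b >= n || t.c >= n) continue;
    // orient counter-clockwise
    double ax = x[t.a], ay = y[t.a], bx = x[t.b], by = y[t.b];
    double cx = x[t.c], cy = y[t.c];
    double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (det >= 0) {
      out(row, 0) = t.a + 1; out(row, 1) = t.b + 1; out(row, 2) = t.c + 1;
    } else {
      out(row, 0) = t.a + 1; out(row, 1) = t.c + 1; out(row, 2) = t.b + 1;
    }
    ++row;
  }
  return out;
}
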