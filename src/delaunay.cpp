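#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation.
//
// Points are expected pre-jittered by the caller when degeneracies
// (cocircular/collinear subsets) are possible; the in-circle test below is
// plain double arithmetic.  The caller also removes duplicate points.

struct Tri {
  int a, b, c;
  bool alive;
};

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// true when d lies inside the circumcircle of CCW triangle (a,b,c)
static inline bool in_circle(double ax, double ay, double bx, double by,
                             double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy)
             - ady * (bdx * cd - bd * cdx)
             + ad  * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points");

  // bounding box and super-triangle
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double dx = xmax - xmin, dy = ymax - ymin;
  double dmax = (dx > dy ? dx : dy);
  if (dmax <= 0) stop("degenerate point set");
  double midx = (xmin + xmax) / 2, midy = (ymin + ymax) / 2;

  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  double M = 1.0e8 * dmax;
  px[n]     = midx - 2.0 * M; py[n]     = midy - M;
  px[n + 1] = midx + 2.0 * M; py[n + 1] = midy - M;
  px[n + 2] = midx;           py[n + 2] = midy + 2.0 * M;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  typedef std::pair<int, int> Edge;

  for (int i = 0; i < n; ++i) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &T = tris[t];
      if (in_circle(px[T.a], py[T.a], px[T.b], py[T.b],
                    px[T.c], py[T.c], px[i], py[i]))
        bad.push_back((int)t);
    }
    // boundary of the cavity: edges used by exactly one bad triangle
    std::map<Edge, int> ecount;
    std::map<Edge, Edge> eorient;  // keep original direction
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri &T = tris[bad[k]];
      int vs[3] = {T.a, T.b, T.c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        Edge key = (u < v) ? Edge(u, v) : Edge(v, u);
        ecount[key]++;
        eorient[key] = Edge(u, v);
      }
      tris[bad[k]].alive = false;
    }
    for (std::map<Edge, int>::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue;
      Edge d = eorient[it->first];
      int u = d.first, v = d.second;
      // new triangle (u, v, i); enforce CCW
      if (orient2d(px[u], py[u], px[v], py[v], px[i], py[i]) < 0) {
        int tmp = u; u = v; v = tmp;
      }
      tris.push_back({u, v, i, true});
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    const Tri &T = tris[t];
    if (T.a >= n || T.b >= n || T.c >= n) continue;
    out(r, 0) = T.a + 1; out(r, 1) = T.b + 1; out(r, 2) = T.c + 1;
    ++r;
  }
  return out;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nd = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nd; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
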