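// Triangular meshing of a multiply-connected planar region: unstructured
// Delaunay triangulation (Bowyer-Watson) of boundary samples plus an interior
// lattice, followed by Ruppert-style quality refinement (circumcenter
// insertion with diametral-circle segment protection).  Holes (cells and
// vessels) are supplied as closed polygons; the region meshed is the outer
// square minus the holes.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Tri {
  int v[3];
  int a[3];       // a[i] = triangle opposite v[i], -1 if none
  bool alive;
  signed char inside;   // -1 unknown, 0 outside EES, 1 inside
};

struct Seg {
  int a, b;
  int tag;        // 0 outer, 1 vessel, 2 cell
  int sid;        // shape index, -1 for outer
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (ax - cx) * (by - cy) - (ay - cy) * (bx - cx);
}

// ---------------------------------------------------------------------------
// hole container with a uniform bucket grid for point-in-domain queries
struct HoleSet {
  std::vector<std::vector<double> > hx, hy;   // rings (not closed)
  std::vector<double> x0, y0, x1, y1;         // bboxes
  double side;
  double cell;
  int nx, ny;
  std::vector<std::vector<int> > grid;

  void build(const List& polys, double side_, double clearance) {
    side = side_;
    int nh = polys.size();
    hx.resize(nh); hy.resize(nh);
    x0.resize(nh); y0.resize(nh); x1.resize(nh); y1.resize(nh);
    double maxext = 1e-6;
    for (int k = 0; k < nh; ++k) {
      NumericMatrix P = polys[k];
      int n = P.nrow();
      hx[k].resize(n); hy[k].resize(n);
      double a0 = 1e300, b0 = 1e300, a1 = -1e300, b1 = -1e300;
      for (int i = 0; i < n; ++i) {
        hx[k][i] = P(i, 0); hy[k][i] = P(i, 1);
        a0 = std::min(a0, P(i, 0)); a1 = std::max(a1, P(i, 0));
        b0 = std::min(b0, P(i, 1)); b1 = std::max(b1, P(i, 1));
      }
      x0[k] = a0; y0[k] = b0; x1[k] = a1; y1[k] = b1;
      maxext = std::max(maxext, std::max(a1 - a0, b1 - b0));
    }
    cell = std::max(maxext * 0.75, side / 256.0);
    nx = std::max(1, (int)std::ceil(side / cell));
    ny = nx;
    grid.assign((size_t)nx * ny, std::vector<int>());
    for (int k = 0; k < nh; ++k) {
      int i0 = std::max(0, (int)std::floor((x0[k] - clearance) / cell));
      int i1 = std::min(nx - 1, (int)std::floor((x1[k] + clearance) / cell));
      int j0 = std::max(0, (int)std::floor((y0[k] - clearance) / cell));
      int j1 = std::min(ny - 1, (int)std::floor((y1[k] + clearance) / cell));
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          grid[(size_t)j * nx + i].push_back(k);
    }
  }

  bool inPoly(int k, double px, double py) const {
    // crossing number
    const std::vector<double>& X = hx[k];
    const std::vector<double>& Y = hy[k];
    int n = X.size();
    bool in = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      if (((Y[i] > py) != (Y[j] > py)) &&
          (px < (X[j] - X[i]) * (py - Y[i]) / (Y[j] - Y[i]) + X[i]))
        in = !in;
    }
    return in;
  }

  const std::vector<int>& bucket(double px, double py) const {
    int i = std::min(nx - 1, std::max(0, (int)std::floor(px / cell)));
    int j = std::min(ny - 1, std::max(0, (int)std::floor(py / cell)));
    return grid[(size_t)j * nx + i];
  }

  // true if (px,py) lies in the EES (inside square, outside all holes)
  bool insideDomain(double px, double py) const {
    if (px <= 0 || py <= 0 || px >= side || py >= side) return false;
    const std::vector<int>& cand = bucket(px, py);
    for (size_t q = 0; q < cand.size(); ++q) {
      int k = cand[q];
      if (px < x0[k] || px > x1[k] || py < y0[k] || py > y1[k]) continue;
      if (inPoly(k, px, py)) return false;
    }
    return true;
  }

  // minimum distance from point to any nearby hole boundary; returns a value
  // > thresh when no hole is near.  Negative when inside a hole.
  double distance(double px, double py, double thresh) const {
    const std::vector<int>& cand = bucket(px, py);
    double best = thresh * 4.0;
    for (size_t q = 0; q < cand.size(); ++q) {
      int k = cand[q];
      if (px < x0[k] - thresh || px > x1[k] + thresh ||
          py < y0[k] - thresh || py > y1[k] + thresh) continue;
      const std::vector<double>& X = hx[k];
      const std::vector<double>& Y = hy[k];
      int n = X.size();
      double dmin = 1e300;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double ex = X[i] - X[j], ey = Y[i] - Y[j];
        double qx = px - X[j], qy = py - Y[j];
        double L2 = ex * ex + ey * ey;
        double t = (L2 > 0) ? std::max(0.0, std::min(1.0, (qx * ex + qy * ey) / L2)) : 0.0;
        double dx = qx - t * ex, dy = qy - t * ey;
        dmin = std::min(dmin, dx * dx + dy * dy);
      }
      dmin = std::sqrt(dmin);
      if (inPoly(k, px, py)) dmin = -dmin;
      best = std::min(best, dmin);
    }
    return best;
  }
};

// ---------------------------------------------------------------------------
struct Mesher {
  std::vector<double> X, Y;
  std::vector<Tri> tris;
  std::vector<Seg> segs;
  HoleSet holes;
  double side, h;
  double minAngleRad, areaMax, minSegLen;
  int maxVerts;
  int hint;
  std::vector<int> mark;    // visit stamps for cavity BFS
  int stamp;
  // uniform grids for vertices and segments (cell = h)
  double gcell; int gnx;
  std::unordered_map<int64_t, std::vector<int> > vgrid;
  std::unordered_map<int64_t, std::vector<int> > sgrid;
  std::vector<int> newTris;

  int64_t gkey(double x, double y) const {
    int i = (int)std::floor(x / gcell), j = (int)std::floor(y / gcell);
    return ((int64_t)j << 32) ^ (int64_t)(uint32_t)i;
  }
  void vgridAdd(int v) { vgrid[gkey(X[v], Y[v])].push_back(v); }
  void sgridAdd(int s) {
    double mx = 0.5 * (X[segs[s].a] + X[segs[s].b]);
    double my = 0.5 * (Y[segs[s].a] + Y[segs[s].b]);
    sgrid[gkey(mx, my)].push_back(s);
  }

  bool inCircum(int t, double px, double py) const {
    const Tri& T = tris[t];
    // super vertices are 0,1,2 and far away; plain arithmetic suffices
    long double adx = X[T.v[0]] - px, ady = Y[T.v[0]] - py;
    long double bdx = X[T.v[1]] - px, bdy = Y[T.v[1]] - py;
    long double cdx = X[T.v[2]] - px, cdy = Y[T.v[2]] - py;
    long double ad = adx * adx + ady * ady;
    long double bd = bdx * bdx + bdy * bdy;
    long double cd = cdx * cdx + cdy * cdy;
    long double det = adx * (bdy * cd - cdy * bd)
                    - ady * (bdx * cd - cdx * bd)
                    + ad * (bdx * cdy - cdx * bdy);
    long double mag = std::fabs((double)(adx * bdy * cd)) + std::fabs((double)(cdy * bd * adx))
                    + std::fabs((double)(ady * bdx * cd)) + std::fabs((double)(cdx * bd * ady))
                    + std::fabs((double)(ad * bdx * cdy)) + std::fabs((double)(ad * cdx * bdy));
    return det > 1e-14L * mag;
  }

  int locate(double px, double py) {
    int t = hint;
    if (t < 0 || t >= (int)tris.size() || !tris[t].alive) {
      t = -1;
      for (int i = (int)tris.size() - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
    }
    int steps = 0, cap = (int)tris.size() + 64;
    while (steps++ < cap) {
      const Tri& T = tris[t];
      int nxt = -1;
      for (int e = 0; e < 3; ++e) {
        int u = T.v[(e + 1) % 3], w = T.v[(e + 2) % 3];
        if (orient2d(X[u], Y[u], X[w], Y[w], px, py) < 0) { nxt = T.a[e]; break; }
      }
      if (nxt < 0) return t;
      t = nxt;
    }
    // fallback linear scan
    for (int i = 0; i < (int)tris.size(); ++i) {
      if (!tris[i].alive) continue;
      const Tri& T = tris[i];
      bool ok = true;
      for (int e = 0; e < 3 && ok; ++e) {
        int u = T.v[(e + 1) % 3], w = T.v[(e + 2) % 3];
        if (orient2d(X[u], Y[u], X[w], Y[w], px, py) < -1e-18) ok = false;
      }
      if (ok) return i;
    }
    return -1;
  }

  // Bowyer-Watson insertion; returns new vertex id or -1 on failure/duplicate
  int insert(double px, double py) {
    if ((int)X.size() >= maxVerts) return -1;
    int t0 = locate(px, py);
    if (t0 < 0) return -1;
    // duplicate guard
    for (int e = 0; e < 3; ++e) {
      int v = tris[t0].v[e];
      double dx = X[v] - px, dy = Y[v] - py;
      if (dx * dx + dy * dy < 1e-22) return -1;
    }
    ++stamp;
    std::vector<int> cavity;
    std::vector<int> stk;
    stk.push_back(t0);
    mark.resize(tris.size() + 8, 0);
    mark[t0] = stamp;
    while (!stk.empty()) {
      int t = stk.back(); stk.pop_back();
      cavity.push_back(t);
      for (int e = 0; e < 3; ++e) {
        int n = tris[t].a[e];
        if (n < 0 || mark[n] == stamp || !tris[n].alive) continue;
        if (inCircum(n, px, py)) { mark[n] = stamp; stk.push_back(n); }
      }
    }
    // boundary edges of the cavity
    struct BEdge { int u, w, outer, oslot; };
    std::vector<BEdge> bnd;
    for (size_t ci = 0; ci < cavity.size(); ++ci) {
      int t = cavity[ci];
      for (int e = 0; e < 3; ++e) {
        int n = tris[t].a[e];
        if (n >= 0 && mark[n] == stamp) continue;
        int oslot = -1;
        if (n >= 0) for (int s = 0; s < 3; ++s) if (tris[n].a[s] == t) oslot = s;
        BEdge be; be.u = tris[t].v[(e + 1) % 3]; be.w = tris[t].v[(e + 2) % 3];
        be.outer = n; be.oslot = oslot;
        bnd.push_back(be);
      }
    }
    // cavity repair: every boundary edge must see p on its interior side
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t bi = 0; bi < bnd.size() && !changed; ++bi) {
        if (orient2d(X[bnd[bi].u], Y[bnd[bi].u], X[bnd[bi].w], Y[bnd[bi].w], px, py) <= 0) {
          // find the cavity triangle owning this edge and evict it
          int evict = -1;
          for (size_t ci = 0; ci < cavity.size(); ++ci) {
            int t = cavity[ci];
            for (int e = 0; e < 3; ++e) {
              if (tris[t].v[(e + 1) % 3] == bnd[bi].u && tris[t].v[(e + 2) % 3] == bnd[bi].w) {
                evict = t; break;
              }
            }
            if (evict >= 0) break;
          }
          if (evict < 0 || cavity.size() <= 1) return -1;   // degenerate; refuse
          mark[evict] = 0;
          cavity.erase(std::remove(cavity.begin(), cavity.end(), evict), cavity.end());
          bnd.clear();
          for (size_t ci = 0; ci < cavity.size(); ++ci) {
            int t = cavity[ci];
            for (int e = 0; e < 3; ++e) {
              int n = tris[t].a[e];
              if (n >= 0 && mark[n] == stamp) continue;
              int oslot = -1;
              if (n >= 0) for (int s = 0; s < 3; ++s) if (tris[n].a[s] == t) oslot = s;
              BEdge be; be.u = tris[t].v[(e + 1) % 3]; be.w = tris[t].v[(e + 2) % 3];
              be.outer = n; be.oslot = oslot;
              bnd.push_back(be);
            }
          }
          changed = true;
        }
      }
    }
    int p = (int)X.size();
    X.push_back(px); Y.push_back(py);
    for (size_t ci = 0; ci < cavity.size(); ++ci) tris[cavity[ci]].alive = false;
    newTris.clear();
    std::unordered_map<int, std::pair<int, int> > link;  // shared vertex -> (tri, slot)
    for (size_t bi = 0; bi < bnd.size(); ++bi) {
      Tri T;
      T.v[0] = p; T.v[1] = bnd[bi].u; T.v[2] = bnd[bi].w;
      T.a[0] = bnd[bi].outer; T.a[1] = -1; T.a[2] = -1;
      T.alive = true; T.inside = -1;
      int ti = (int)tris.size();
      tris.push_back(T);
      mark.push_back(0);
      if (bnd[bi].outer >= 0 && bnd[bi].oslot >= 0) tris[bnd[bi].outer].a[bnd[bi].oslot] = ti;
      // edge (w,p) keyed by w -> slot 1 ; edge (p,u) keyed by u -> slot 2
      std::unordered_map<int, std::pair<int, int> >::iterator it;
      it = link.find(bnd[bi].w);
      if (it != link.end()) { tris[ti].a[1] = it->second.first; tris[it->second.first].a[it->second.second] = ti; link.erase(it); }
      else link[bnd[bi].w] = std::make_pair(ti, 1);
      it = link.find(bnd[bi].u);
      if (it != link.end()) { tris[ti].a[2] = it->second.first; tris[it->second.first].a[it->second.second] = ti; link.erase(it); }
      else link[bnd[bi].u] = std::make_pair(ti, 2);
      newTris.push_back(ti);
    }
    hint = newTris.empty() ? hint : newTris[0];
    vgridAdd(p);
    return p;
  }

  void setInside(int t) {
    const Tri& T = tris[t];
    if (T.v[0] < 3 || T.v[1] < 3 || T.v[2] < 3) { tris[t].inside = 0; return; }
    double cx = (X[T.v[0]] + X[T.v[1]] + X[T.v[2]]) / 3.0;
    double cy = (Y[T.v[0]] + Y[T.v[1]] + Y[T.v[2]]) / 3.0;
    tris[t].inside = holes.insideDomain(cx, cy) ? 1 : 0;
  }

  double area(int t) const {
    const Tri& T = tris[t];
    return 0.5 * orient2d(X[T.v[0]], Y[T.v[0]], X[T.v[1]], Y[T.v[1]], X[T.v[2]], Y[T.v[2]]);
  }

  double minAngle(int t) const {
    const Tri& T = tris[t];
    double l2[3];
    for (int e = 0; e < 3; ++e) {
      int u = T.v[(e + 1) % 3], w = T.v[(e + 2) % 3];
      double dx = X[u] - X[w], dy = Y[u] - Y[w];
      l2[e] = dx * dx + dy * dy;
    }
    double A = std::fabs(area(t));
    double best = 1e30;
    for (int e = 0; e < 3; ++e) {
      // angle at vertex e is opposite edge e ; sin = 2A/(b*c)
      double b = std::sqrt(l2[(e + 1) % 3]), c = std::sqrt(l2[(e + 2) % 3]);
      double cosv = (l2[(e + 1) % 3] + l2[(e + 2) % 3] - l2[e]) / (2.0 * b * c);
      cosv = std::max(-1.0, std::min(1.0, cosv));
      double sinv = 2.0 * A / (b * c);
      sinv = std::max(-1.0, std::min(1.0, sinv));
      double ang = std::atan2(sinv, cosv);
      best = std::min(best, ang);
    }
    return best;
  }

  bool circumcenter(int t, double& cx, double& cy, double& r2) const {
    const Tri& T = tris[t];
    double ax = X[T.v[0]], ay = Y[T.v[0]];
    double bx = X[T.v[1]] - ax, by = Y[T.v[1]] - ay;
    double qx = X[T.v[2]] - ax, qy = Y[T.v[2]] - ay;
    double d = 2.0 * (bx * qy - by * qx);
    if (std::fabs(d) < 1e-30) return false;
    double b2 = bx * bx + by * by, q2 = qx * qx + qy * qy;
    double ux = (qy * b2 - by * q2) / d;
    double uy = (bx * q2 - qx * b2) / d;
    cx = ax + ux; cy = ay + uy; r2 = ux * ux + uy * uy;
    return true;
  }

  // segments whose diametral circle contains (px,py)
  void encroached(double px, double py, std::vector<int>& out) const {
    out.clear();
    int ic = (int)std::floor(px / gcell), jc = (int)std::floor(py / gcell);
    for (int j = jc - 1; j <= jc + 1; ++j)
      for (int i = ic - 1; i <= ic + 1; ++i) {
        int64_t key = ((int64_t)j << 32) ^ (int64_t)(uint32_t)i;
        std::unordered_map<int64_t, std::vector<int> >::const_iterator it = sgrid.find(key);
        if (it == sgrid.end()) continue;
        for (size_t q = 0; q < it->second.size(); ++q) {
          int s = it->second[q];
          if (!segs[s].alive) continue;
          double mx = 0.5 * (X[segs[s].a] + X[segs[s].b]);
          double my = 0.5 * (Y[segs[s].a] + Y[segs[s].b]);
          double dx = X[segs[s].a] - X[segs[s].b], dy = Y[segs[s].a] - Y[segs[s].b];
          double r2 = 0.25 * (dx * dx + dy * dy);
          double d2 = (px - mx) * (px - mx) + (py - my) * (py - my);
          if (d2 < r2 * (1.0 - 1e-12)) out.push_back(s);
        }
      }
  }

  // does any existing vertex (other than endpoints) encroach segment s?
  bool vertexEncroaches(int s) const {
    double mx = 0.5 * (X[segs[s].a] + X[segs[s].b]);
    double my = 0.5 * (Y[segs[s].a] + Y[segs[s].b]);
    double dx = X[segs[s].a] - X[segs[s].b], dy = Y[segs[s].a] - Y[segs[s].b];
    double r2 = 0.25 * (dx * dx + dy * dy);
    int ic = (int)std::floor(mx / gcell), jc = (int)std::floor(my / gcell);
    for (int j = jc - 1; j <= jc + 1; ++j)
      for (int i = ic - 1; i <= ic + 1; ++i) {
        int64_t key = ((int64_t)j << 32) ^ (int64_t)(uint32_t)i;
        std::unordered_map<int64_t, std::vector<int> >::const_iterator it = vgrid.find(key);
        if (it == vgrid.end()) continue;
        for (size_t q = 0; q < it->second.size(); ++q) {
          int v = it->second[q];
          if (v == segs[s].a || v == segs[s].b) continue;
          double d2 = (X[v] - mx) * (X[v] - mx) + (Y[v] - my) * (Y[v] - my);
          if (d2 < r2 * (1.0 - 1e-10)) return true;
        }
      }
    return false;
  }

  // first alive segment crossed by the path (x0,y0)->(x1,y1), or -1
  int crossedSegment(double x0, double y0, double x1, double y1) const {
    double lox = std::min(x0, x1) - gcell, hix = std::max(x0, x1) + gcell;
    double loy = std::min(y0, y1) - gcell, hiy = std::max(y0, y1) + gcell;
    int i0 = (int)std::floor(lox / gcell), i1 = (int)std::floor(hix / gcell);
    int j0 = (int)std::floor(loy / gcell), j1 = (int)std::floor(hiy / gcell);
    int best = -1;
    double bestT = 2.0;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        int64_t key = ((int64_t)j << 32) ^ (int64_t)(uint32_t)i;
        std::unordered_map<int64_t, std::vector<int> >::const_iterator it = sgrid.find(key);
        if (it == sgrid.end()) continue;
        for (size_t q = 0; q < it->second.size(); ++q) {
          int s = it->second[q];
          if (!segs[s].alive) continue;
          double ax = X[segs[s].a], ay = Y[segs[s].a];
          double bx = X[segs[s].b], by = Y[segs[s].b];
          double d1 = orient2d(x0, y0, x1, y1, ax, ay);
          double d2 = orient2d(x0, y0, x1, y1, bx, by);
          if (d1 * d2 > 0) continue;
          double d3 = orient2d(ax, ay, bx, by, x0, y0);
          double d4 = orient2d(ax, ay, bx, by, x1, y1);
          if (d3 * d4 > 0) continue;
          double denom = d3 - d4;
          double t = (std::fabs(denom) > 1e-300) ? d3 / denom : 0.0;
          if (t < bestT) { bestT = t; best = s; }
        }
      }
    return best;
  }

  double segLen(int s) const {
    double dx = X[segs[s].a] - X[segs[s].b], dy = Y[segs[s].a] - Y[segs[s].b];
    return std::sqrt(dx * dx + dy * dy);
  }

  // split s at midpoint, return new vertex (or -1); children pushed to queue
  int splitSeg(int s, std::queue<int>& segQueue, std::queue<int>& triQueue) {
    if (segLen(s) < 2.0 * minSegLen) return -1;
    double mx = 0.5 * (X[segs[s].a] + X[segs[s].b]);
    double my = 0.5 * (Y[segs[s].a] + Y[segs[s].b]);
    int m = insert(mx, my);
    if (m < 0) return -1;
    segs[s].alive = false;
    Seg s1; s1.a = segs[s].a; s1.b = m; s1.tag = segs[s].tag; s1.sid = segs[s].sid; s1.alive = true;
    Seg s2; s2.a = m; s2.b = segs[s].b; s2.tag = segs[s].tag; s2.sid = segs[s].sid; s2.alive = true;
    int i1 = (int)segs.size(); segs.push_back(s1); sgridAdd(i1); segQueue.push(i1);
    int i2 = (int)segs.size(); segs.push_back(s2); sgridAdd(i2); segQueue.push(i2);
    for (size_t q = 0; q < newTris.size(); ++q) {
      setInside(newTris[q]);
      triQueue.push(newTris[q]);
    }
    return m;
  }

  bool isBad(int t) const {
    if (!tris[t].alive || tris[t].inside != 1) return false;
    double A = std::fabs(area(t));
    if (A > areaMax) return true;
    return minAngle(t) < minAngleRad;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_mesh_ees")]]
List cpp_mesh_ees(NumericMatrix bnd_pts, IntegerMatrix seg_idx,
                  IntegerVector seg_tag, IntegerVector seg_sid,
                  List hole_polys, double side, double h,
                  double min_angle_deg = 20.0, double area_max_factor = 1.3,
                  double lattice_clearance = 0.6, int max_verts = 400000,
                  double min_seg_len_frac = 0.02) {
  Mesher M;
  M.side = side; M.h = h;
  M.minAngleRad = min_angle_deg * M_PI / 180.0;
  M.areaMax = area_max_factor * 0.4330127018922193 * h * h;
  M.minSegLen = std::max(min_seg_len_frac * h, 1e-5);
  M.maxVerts = max_verts;
  M.stamp = 0;
  M.gcell = h; M.gnx = (int)std::ceil(side / h);
  M.holes.build(hole_polys, side, lattice_clearance * h);

  // ---- collect points: boundary first (ids fixed), then interior lattice
  int nb = bnd_pts.nrow();
  std::vector<double> ptx, pty;
  ptx.reserve(nb + 1024); pty.reserve(nb + 1024);
  for (int i = 0; i < nb; ++i) { ptx.push_back(bnd_pts(i, 0)); pty.push_back(bnd_pts(i, 1)); }
  // hexagonal interior lattice with deterministic jitter
  {
    uint64_t rng = 88172645463325252ULL;
    double dy = h * 0.8660254037844386;
    int nrows = (int)std::floor(side / dy);
    for (int r = 1; r <= nrows; ++r) {
      double y = r * dy;
      double xoff = (r % 2 == 0) ? 0.0 : 0.5 * h;
      int ncols = (int)std::floor((side - xoff) / h);
      for (int c = 0; c <= ncols; ++c) {
        double x = xoff + c * h;
        rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
        double j1 = ((double)(rng % 20001) / 10000.0 - 1.0) * 0.04 * h;
        rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
        double j2 = ((double)(rng % 20001) / 10000.0 - 1.0) * 0.04 * h;
        x += j1; y += j2;
        double wall = std::min(std::min(x, y), std::min(side - x, side - y));
        if (wall < lattice_clearance * h) { y -= j2; continue; }
        if (M.holes.distance(x, y, lattice_clearance * h) < lattice_clearance * h) { y -= j2; continue; }
        ptx.push_back(x); pty.push_back(y);
        y -= j2;
      }
    }
  }
  int ntot = (int)ptx.size();

  // ---- super triangle
  double R = side * 40.0, cx = side / 2.0, cy = side / 2.0;
  M.X.push_back(cx - R); M.Y.push_back(cy - 0.6 * R);
  M.X.push_back(cx + R); M.Y.push_back(cy - 0.6 * R);
  M.X.push_back(cx);     M.Y.push_back(cy + R);
  Tri T0; T0.v[0] = 0; T0.v[1] = 1; T0.v[2] = 2;
  T0.a[0] = T0.a[1] = T0.a[2] = -1; T0.alive = true; T0.inside = -1;
  M.tris.push_back(T0);
  M.mark.push_back(0);
  M.hint = 0;

  // ---- insertion order: spatial sort for walk locality
  std::vector<int> order(ntot);
  for (int i = 0; i < ntot; ++i) order[i] = i;
  double oc = h * 4.0;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    int ia = (int)(ptx[a] / oc), ja = (int)(pty[a] / oc);
    int ib = (int)(ptx[b] / oc), jb = (int)(pty[b] / oc);
    if (ja != jb) return ja < jb;
    int ka = (ja % 2 == 0) ? ia : -ia;   // boustrophedon
    int kb = (ja % 2 == 0) ? ib : -ib;
    if (ka != kb) return ka < kb;
    return a < b;
  });
  std::vector<int> vid(ntot, -1);
  for (int q = 0; q < ntot; ++q) {
    int i = order[q];
    vid[i] = M.insert(ptx[i], pty[i]);
  }
  for (int i = 0; i < nb; ++i)
    if (vid[i] < 0) stop("meshing failure: could not insert boundary point %d", i + 1);

  // ---- register segments
  std::queue<int> segQueue, triQueue;
  for (int s = 0; s < seg_idx.nrow(); ++s) {
    Seg sg;
    sg.a = vid[seg_idx(s, 0) - 1];
    sg.b = vid[seg_idx(s, 1) - 1];
    sg.tag = seg_tag[s]; sg.sid = seg_sid[s]; sg.alive = true;
    int id = (int)M.segs.size();
    M.segs.push_back(sg);
    M.sgridAdd(id);
    segQueue.push(id);
  }

  // ---- segment recovery: ensure every segment is an edge (split if missing)
  for (int round = 0; round < 24; ++round) {
    // edge set of current triangulation
    std::unordered_map<int64_t, int> edges;
    for (size_t t = 0; t < M.tris.size(); ++t) {
      if (!M.tris[t].alive) continue;
      for (int e = 0; e < 3; ++e) {
        int u = M.tris[t].v[(e + 1) % 3], w = M.tris[t].v[(e + 2) % 3];
        int64_t key = ((int64_t)std::min(u, w) << 32) | (uint32_t)std::max(u, w);
        edges[key] = (int)t;
      }
    }
    bool allok = true;
    size_t nseg = M.segs.size();
    for (size_t s = 0; s < nseg; ++s) {
      if (!M.segs[s].alive) continue;
      int u = M.segs[s].a, w = M.segs[s].b;
      int64_t key = ((int64_t)std::min(u, w) << 32) | (uint32_t)std::max(u, w);
      if (edges.find(key) == edges.end()) {
        allok = false;
        if (M.splitSeg((int)s, segQueue, triQueue) < 0)
          stop("meshing failure: cannot recover a boundary segment (geometry too tight)");
      }
    }
    if (allok) break;
    if (round == 23) stop("meshing failure: boundary segment recovery did not converge");
  }

  // ---- initial encroachment enforcement (diametral-circle protection)
  {
    int guard = 0;
    while (!segQueue.empty() && guard++ < 20 * ntot) {
      int s = segQueue.front(); segQueue.pop();
      if (!M.segs[s].alive) continue;
      if (M.segLen(s) < 2.0 * M.minSegLen) continue;
      if (M.vertexEncroaches(s)) M.splitSeg(s, segQueue, triQueue);
    }
  }

  // ---- classify triangles
  for (size_t t = 0; t < M.tris.size(); ++t)
    if (M.tris[t].alive) M.setInside((int)t);

  // ---- Ruppert refinement
  {
    while (!triQueue.empty()) triQueue.pop();
    for (size_t t = 0; t < M.tris.size(); ++t)
      if (M.isBad((int)t)) triQueue.push((int)t);
    std::vector<int> enc;
    int guard = 0, guardMax = 40 * ntot + 200000;
    while (!triQueue.empty() && (int)M.X.size() < max_verts && guard++ < guardMax) {
      int t = triQueue.front(); triQueue.pop();
      if (!M.isBad(t)) continue;
      double ccx, ccy, r2;
      if (!M.circumcenter(t, ccx, ccy, r2)) continue;
      if (r2 < M.minSegLen * M.minSegLen) continue;
      M.encroached(ccx, ccy, enc);
      if (!enc.empty()) {
        bool split = false;
        for (size_t q = 0; q < enc.size(); ++q) {
          if (!M.segs[enc[q]].alive) continue;
          if (M.splitSeg(enc[q], segQueue, triQueue) >= 0) split = true;
        }
        // drain cascade of encroached children
        int g2 = 0;
        while (!segQueue.empty() && g2++ < 4 * ntot) {
          int s = segQueue.front(); segQueue.pop();
          if (!M.segs[s].alive) continue;
          if (M.segLen(s) < 2.0 * M.minSegLen) continue;
          if (M.vertexEncroaches(s)) M.splitSeg(s, segQueue, triQueue);
        }
        if (split && M.tris[t].alive) triQueue.push(t);
        continue;
      }
      if (!M.holes.insideDomain(ccx, ccy)) {
        // circumcenter escaped through a boundary: split the crossed segment
        const Tri& T = M.tris[t];
        double gx = (M.X[T.v[0]] + M.X[T.v[1]] + M.X[T.v[2]]) / 3.0;
        double gy = (M.Y[T.v[0]] + M.Y[T.v[1]] + M.Y[T.v[2]]) / 3.0;
        int s = M.crossedSegment(gx, gy, ccx, ccy);
        if (s >= 0 && M.splitSeg(s, segQueue, triQueue) >= 0) {
          int g2 = 0;
          while (!segQueue.empty() && g2++ < 4 * ntot) {
            int s2 = segQueue.front(); segQueue.pop();
            if (!M.segs[s2].alive) continue;
            if (M.segLen(s2) < 2.0 * M.minSegLen) continue;
            if (M.vertexEncroaches(s2)) M.splitSeg(s2, segQueue, triQueue);
          }
          if (M.tris[t].alive) triQueue.push(t);
        }
        continue;
      }
      int p = M.insert(ccx, ccy);
      if (p < 0) continue;
      for (size_t q = 0; q < M.newTris.size(); ++q) {
        M.setInside(M.newTris[q]);
        if (M.isBad(M.newTris[q])) triQueue.push(M.newTris[q]);
      }
    }
  }

  // ---- outputs: compact inside triangles
  std::vector<int> remap(M.X.size(), -1);
  std::vector<int> tcount;
  int nvOut = 0, ntOut = 0;
  for (size_t t = 0; t < M.tris.size(); ++t)
    if (M.tris[t].alive && M.tris[t].inside == 1) ++ntOut;
  IntegerMatrix triOut(ntOut, 3);
  {
    int r = 0;
    for (size_t t = 0; t < M.tris.size(); ++t) {
      if (!(M.tris[t].alive && M.tris[t].inside == 1)) continue;
      for (int e = 0; e < 3; ++e) {
        int v = M.tris[t].v[e];
        if (remap[v] < 0) remap[v] = nvOut++;
        triOut(r, e) = remap[v] + 1;
      }
      ++r;
    }
  }
  NumericMatrix nodesOut(nvOut, 2);
  for (size_t v = 0; v < M.X.size(); ++v)
    if (remap[v] >= 0) { nodesOut(remap[v], 0) = M.X[v]; nodesOut(remap[v], 1) = M.Y[v]; }
  int nsOut = 0;
  for (size_t s = 0; s < M.segs.size(); ++s)
    if (M.segs[s].alive && remap[M.segs[s].a] >= 0 && remap[M.segs[s].b] >= 0) ++nsOut;
  IntegerMatrix segOut(nsOut, 2);
  IntegerVector tagOut(nsOut), sidOut(nsOut);
  {
    int r = 0;
    for (size_t s = 0; s < M.segs.size(); ++s) {
      if (!(M.segs[s].alive && remap[M.segs[s].a] >= 0 && remap[M.segs[s].b] >= 0)) continue;
      segOut(r, 0) = remap[M.segs[s].a] + 1;
      segOut(r, 1) = remap[M.segs[s].b] + 1;
      tagOut[r] = M.segs[s].tag; sidOut[r] = M.segs[s].sid;
      ++r;
    }
  }
  int nBad = 0;
  double worst = 1e30;
  for (size_t t = 0; t < M.tris.size(); ++t) {
    if (!(M.tris[t].alive && M.tris[t].inside == 1)) continue;
    double a = M.minAngle((int)t);
    worst = std::min(worst, a);
    if (a < M.minAngleRad - 1e-9) ++nBad;
  }
  return List::create(
    _["nodes"] = nodesOut,
    _["triangles"] = triOut,
    _["segments"] = segOut,
    _["seg_tag"] = tagOut,
    _["seg_sid"] = sidOut,
    _["n_bad_quality"] = nBad,
    _["min_angle_deg"] = worst * 180.0 / M_PI,
    _["n_vertices_total"] = (int)M.X.size());
}
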