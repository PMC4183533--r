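// Dense non-overlapping placement of convex shapes (ellipse cells around
// fixed circular vessels) inside a square tile.  Cells are seeded at random
// positions and relaxed by pairwise push-apart moves (SAT minimum translation
// vector on polygonized, halo-inflated shapes) until no residual overlap.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;   // centered at origin
  double rad;                 // circumradius
  double extx, exty;          // axis-aligned half extents
};

Poly fromMatrix(const NumericMatrix& P) {
  Poly p;
  int n = P.nrow();
  p.x.resize(n); p.y.resize(n);
  p.rad = 0; p.extx = 0; p.exty = 0;
  for (int i = 0; i < n; ++i) {
    p.x[i] = P(i, 0); p.y[i] = P(i, 1);
    p.rad = std::max(p.rad, std::sqrt(P(i, 0) * P(i, 0) + P(i, 1) * P(i, 1)));
    p.extx = std::max(p.extx, std::fabs(P(i, 0)));
    p.exty = std::max(p.exty, std::fabs(P(i, 1)));
  }
  return p;
}

// SAT overlap of poly A at (axc,ayc) and poly B at (bxc,byc).
// Returns depth > 0 with (nx,ny) the unit push direction for A (away from B)
// when overlapping; returns <= 0 if separated.
double satDepth(const Poly& A, double axc, double ayc,
                const Poly& B, double bxc, double byc,
                double& nx, double& ny) {
  double best = 1e300;
  double bnx = 0, bny = 0;
  const Poly* polys[2] = { &A, &B };
  for (int w = 0; w < 2; ++w) {
    const Poly& P = *polys[w];
    int n = (int)P.x.size();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double ex = P.x[i] - P.x[j], ey = P.y[i] - P.y[j];
      double len = std::sqrt(ex * ex + ey * ey);
      if (len < 1e-300) continue;
      double axn = -ey / len, ayn = ex / len;   // outward-ish normal (sign irrelevant)
      double amin = 1e300, amax = -1e300, bmin = 1e300, bmax = -1e300;
      for (size_t k = 0; k < A.x.size(); ++k) {
        double pr = (A.x[k] + axc) * axn + (A.y[k] + ayc) * ayn;
        amin = std::min(amin, pr); amax = std::max(amax, pr);
      }
      for (size_t k = 0; k < B.x.size(); ++k) {
        double pr = (B.x[k] + bxc) * axn + (B.y[k] + byc) * ayn;
        bmin = std::min(bmin, pr); bmax = std::max(bmax, pr);
      }
      double ov = std::min(amax, bmax) - std::max(amin, bmin);
      if (ov <= 0) { nx = axn; ny = ayn; return ov; }  // separating axis
      if (ov < best) {
        best = ov;
        bnx = axn; bny = ayn;
      }
    }
  }
  // orient push direction from B to A
  double ddx = axc - bxc, ddy = ayc - byc;
  if (ddx * bnx + ddy * bny < 0) { bnx = -bnx; bny = -bny; }
  nx = bnx; ny = bny;
  return best;
}

// exact distance between two separated convex polygons (vertex-edge brute force)
double polyDist(const Poly& A, double axc, double ayc,
                const Poly& B, double bxc, double byc) {
  double best = 1e300;
  for (int w = 0; w < 2; ++w) {
    const Poly& P = (w == 0) ? A : B;
    const Poly& Q = (w == 0) ? B : A;
    double pxc = (w == 0) ? axc : bxc, pyc = (w == 0) ? ayc : byc;
    double qxc = (w == 0) ? bxc : axc, qyc = (w == 0) ? byc : ayc;
    int n = (int)Q.x.size();
    for (size_t k = 0; k < P.x.size(); ++k) {
      double px = P.x[k] + pxc, py = P.y[k] + pyc;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double x1 = Q.x[j] + qxc, y1 = Q.y[j] + qyc;
        double ex = Q.x[i] + qxc - x1, ey = Q.y[i] + qyc - y1;
        double L2 = ex * ex + ey * ey;
        double t = (L2 > 0) ? std::max(0.0, std::min(1.0, ((px - x1) * ex + (py - y1) * ey) / L2)) : 0.0;
        double dx = px - x1 - t * ex, dy = py - y1 - t * ey;
        best = std::min(best, dx * dx + dy * dy);
      }
    }
  }
  return std::sqrt(best);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_relax_cells")]]
List cpp_relax_cells(NumericMatrix centers0, List cellPolys,
                     NumericMatrix vesselCenters, List vesselPolys,
                     double L, int maxSweeps = 4000, double slack = 1e-6) {
  int nc = centers0.nrow();
  int nv = vesselCenters.nrow();
  std::vector<Poly> cells(nc), vessels(nv);
  for (int i = 0; i < nc; ++i) cells[i] = fromMatrix(cellPolys[i]);
  for (int i = 0; i < nv; ++i) vessels[i] = fromMatrix(vesselPolys[i]);
  std::vector<double> cx(nc), cy(nc);
  for (int i = 0; i < nc; ++i) { cx[i] = centers0(i, 0); cy[i] = centers0(i, 1); }
  double maxrad = 1e-9;
  for (int i = 0; i < nc; ++i) maxrad = std::max(maxrad, cells[i].rad);
  for (int i = 0; i < nv; ++i) maxrad = std::max(maxrad, vessels[i].rad);
  double gcell = 2.0 * maxrad;
  int ng = std::max(1, (int)std::floor(L / gcell));
  gcell = L / ng;

  std::vector<std::vector<int> > grid((size_t)ng * ng);
  std::vector<std::vector<int> > vgrid((size_t)ng * ng);
  for (int i = 0; i < nv; ++i) {
    int gx = std::min(ng - 1, std::max(0, (int)(vesselCenters(i, 0) / gcell)));
    int gy = std::min(ng - 1, std::max(0, (int)(vesselCenters(i, 1) / gcell)));
    vgrid[(size_t)gy * ng + gx].push_back(i);
  }

  bool converged = false;
  int sweep = 0;
  std::vector<char> hadOverlap(nc, 0);
  GetRNGstate();
  for (sweep = 0; sweep < maxSweeps; ++sweep) {
    // rebuild cell grid
    for (size_t g = 0; g < grid.size(); ++g) grid[g].clear();
    for (int i = 0; i < nc; ++i) {
      // wall clamp
      cx[i] = std::min(L - cells[i].extx, std::max(cells[i].extx, cx[i]));
      cy[i] = std::min(L - cells[i].exty, std::max(cells[i].exty, cy[i]));
      int gx = std::min(ng - 1, std::max(0, (int)(cx[i] / gcell)));
      int gy = std::min(ng - 1, std::max(0, (int)(cy[i] / gcell)));
      grid[(size_t)gy * ng + gx].push_back(i);
    }
    double maxDepth = 0.0;
    std::fill(hadOverlap.begin(), hadOverlap.end(), 0);
    for (int i = 0; i < nc; ++i) {
      int gx = std::min(ng - 1, std::max(0, (int)(cx[i] / gcell)));
      int gy = std::min(ng - 1, std::max(0, (int)(cy[i] / gcell)));
      for (int jy = std::max(0, gy - 1); jy <= std::min(ng - 1, gy + 1); ++jy)
        for (int jx = std::max(0, gx - 1); jx <= std::min(ng - 1, gx + 1); ++jx) {
          const std::vector<int>& bucket = grid[(size_t)jy * ng + jx];
          for (size_t q = 0; q < bucket.size(); ++q) {
            int j = bucket[q];
            if (j <= i) continue;
            double dx = cx[i] - cx[j], dy = cy[i] - cy[j];
            double rr = cells[i].rad + cells[j].rad;
            if (dx * dx + dy * dy >= rr * rr) continue;
            double nx2, ny2;
            double d = satDepth(cells[i], cx[i], cy[i], cells[j], cx[j], cy[j], nx2, ny2);
            if (d > 0) {
              double mv = 0.5 * d + slack;
              cx[i] += nx2 * mv; cy[i] += ny2 * mv;
              cx[j] -= nx2 * mv; cy[j] -= ny2 * mv;
              maxDepth = std::max(maxDepth, d);
              hadOverlap[i] = hadOverlap[j] = 1;
            }
          }
          const std::vector<int>& vb = vgrid[(size_t)jy * ng + jx];
          for (size_t q = 0; q < vb.size(); ++q) {
            int j = vb[q];
            double dx = cx[i] - vesselCenters(j, 0), dy = cy[i] - vesselCenters(j, 1);
            double rr = cells[i].rad + vessels[j].rad;
            if (dx * dx + dy * dy >= rr * rr) continue;
            double nx2, ny2;
            double d = satDepth(cells[i], cx[i], cy[i],
                                vessels[j], vesselCenters(j, 0), vesselCenters(j, 1), nx2, ny2);
            if (d > 0) {
              cx[i] += nx2 * (d + slack);
              cy[i] += ny2 * (d + slack);
              maxDepth = std::max(maxDepth, d);
              hadOverlap[i] = 1;
            }
          }
        }
    }
    if (maxDepth <= 0.0) { converged = true; break; }
    // occasional jiggle of stuck shapes, growing in amplitude, to escape
    // cyclic jams near the packing limit
    if (sweep > 0 && sweep % 120 == 0) {
      double amp = 6e-4 * (1.0 + sweep / 1500.0);
      for (int i = 0; i < nc; ++i)
        if (hadOverlap[i]) {
          cx[i] += (unif_rand() - 0.5) * amp;
          cy[i] += (unif_rand() - 0.5) * amp;
        }
    }
  }
  PutRNGstate();
  NumericMatrix out(nc, 2);
  for (int i = 0; i < nc; ++i) { out(i, 0) = cx[i]; out(i, 1) = cy[i]; }
  return List::create(_["centers"] = out, _["converged"] = converged,
                      _["sweeps"] = sweep);
}

// [[Rcpp::export(name = ".cpp_min_pair_gap")]]
double cpp_min_pair_gap(List polys) {
  int n = polys.size();
  std::vector<Poly> P(n);
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = polys[i];
    // polys are in world coordinates; recentre for the helper structure
    double mx = 0, my = 0;
    for (int k = 0; k < m.nrow(); ++k) { mx += m(k, 0); my += m(k, 1); }
    mx /= m.nrow(); my /= m.nrow();
    NumericMatrix c(m.nrow(), 2);
    for (int k = 0; k < m.nrow(); ++k) { c(k, 0) = m(k, 0) - mx; c(k, 1) = m(k, 1) - my; }
    P[i] = fromMatrix(c);
    px[i] = mx; py[i] = my;
  }
  double best = 1e300;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = px[i] - px[j], dy = py[i] - py[j];
      double lb = std::sqrt(dx * dx + dy * dy) - P[i].rad - P[j].rad;
      if (lb > best) continue;
      double nx2, ny2;
      double d = satDepth(P[i], px[i], py[i], P[j], px[j], py[j], nx2, ny2);
      if (d > 0) best = std::min(best, -d);          // overlapping: negative depth
      else best = std::min(best, polyDist(P[i], px[i], py[i], P[j], px[j], py[j]));
    }
  return (n < 2) ? R_PosInf : best;
}
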