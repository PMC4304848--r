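// Incremental Bowyer-Watson Delaunay triangulation in 3D with a symbolic
// vertex at infinity (hull facets are handled by orientation predicates, not
// by a finite super-tetrahedron, so no hull simplex can be lost).
//
// Floating-point predicates with scaled tolerances; near-cospherical or
// near-coplanar configurations abort with degenerate = TRUE so the R wrapper
// can apply a deterministic joggle and retry.  Point counts here are protein
// sized (hundreds), so the O(n) conflict scan per insertion is fine.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

const int INF = -1;  // symbolic vertex at infinity

struct Tet {
  int v[4];        // v[3] == INF marks an infinite cell; v[0..2] is its facet
  double cc[3];    // circumcenter (finite cells only)
  double r2;       // squared circumradius (finite cells only)
  bool alive;
};

inline bool is_infinite(const Tet& t) { return t.v[3] == INF; }

double orient3d(const std::array<double, 3>& a, const std::array<double, 3>& b,
                const std::array<double, 3>& c, const std::array<double, 3>& d,
                double& scale) {
  double u[3], v[3], w[3];
  scale = 0.0;
  for (int j = 0; j < 3; ++j) {
    u[j] = b[j] - a[j];
    v[j] = c[j] - a[j];
    w[j] = d[j] - a[j];
    scale = std::max(scale, std::max(std::fabs(u[j]),
                     std::max(std::fabs(v[j]), std::fabs(w[j]))));
  }
  return u[0] * (v[1] * w[2] - v[2] * w[1])
       - u[1] * (v[0] * w[2] - v[2] * w[0])
       + u[2] * (v[0] * w[1] - v[1] * w[0]);
}

// Circumsphere of four points; false when (nearly) coplanar.
bool circumsphere(const std::vector<std::array<double, 3>>& pts,
                  const int v[4], double cc[3], double& r2, double tol) {
  const std::array<double, 3>& a = pts[v[0]];
  double A[3][3], b[3];
  double scale = 0.0;
  for (int i = 0; i < 3; ++i) {
    const std::array<double, 3>& p = pts[v[i + 1]];
    double n2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (p[j] - a[j]);
      n2 += p[j] * p[j] - a[j] * a[j];
      scale = std::max(scale, std::fabs(A[i][j]));
    }
    b[i] = n2;
  }
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
             - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
             + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) <= tol * scale * scale * scale) return false;
  double det0 = b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
              - A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2])
              + A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2]);
  double det1 = A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2])
              - b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
              + A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0]);
  double det2 = A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1])
              - A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0])
              + b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  cc[0] = det0 / det;
  cc[1] = det1 / det;
  cc[2] = det2 / det;
  double d0 = a[0] - cc[0], d1 = a[1] - cc[1], d2 = a[2] - cc[2];
  r2 = d0 * d0 + d1 * d1 + d2 * d2;
  return true;
}

// Circumcircle of a triangle in 3D; false when (nearly) collinear.
bool circumcircle3d(const std::array<double, 3>& a,
                    const std::array<double, 3>& b,
                    const std::array<double, 3>& c,
                    double cc[3], double& r2) {
  double ab[3], ac[3], n[3];
  double scale = 0.0;
  for (int j = 0; j < 3; ++j) {
    ab[j] = b[j] - a[j];
    ac[j] = c[j] - a[j];
    scale = std::max(scale, std::max(std::fabs(ab[j]), std::fabs(ac[j])));
  }
  n[0] = ab[1] * ac[2] - ab[2] * ac[1];
  n[1] = ab[2] * ac[0] - ab[0] * ac[2];
  n[2] = ab[0] * ac[1] - ab[1] * ac[0];
  double n2 = n[0] * n[0] + n[1] * n[1] + n[2] * n[2];
  if (n2 <= 1e-24 * scale * scale * scale * scale) return false;
  double ab2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double ac2 = ac[0] * ac[0] + ac[1] * ac[1] + ac[2] * ac[2];
  double u[3], v[3];
  // u = n x ab, v = ac x n
  u[0] = n[1] * ab[2] - n[2] * ab[1];
  u[1] = n[2] * ab[0] - n[0] * ab[2];
  u[2] = n[0] * ab[1] - n[1] * ab[0];
  v[0] = ac[1] * n[2] - ac[2] * n[1];
  v[1] = ac[2] * n[0] - ac[0] * n[2];
  v[2] = ac[0] * n[1] - ac[1] * n[0];
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) {
    cc[j] = a[j] + (ac2 * u[j] + ab2 * v[j]) / (2.0 * n2);
    double d = a[j] - cc[j];
    r2 += d * d;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix points) {
  const int n = points.nrow();
  if (n < 4) stop("at least 4 points are required");

  std::vector<std::array<double, 3>> pts(n);
  double diam = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 3; ++j) {
      double x = points(i, j);
      if (!R_finite(x)) stop("non-finite coordinate");
      pts[i][j] = x;
    }
  }
  for (int j = 0; j < 3; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo = std::min(lo, pts[i][j]);
      hi = std::max(hi, pts[i][j]);
    }
    diam = std::max(diam, hi - lo);
  }
  if (diam <= 0.0) diam = 1.0;

  const double tol_flat = 1e-10;  // relative coplanarity band
  // Cosphericality band, scaled per tetrahedron: wide enough to catch exact
  // degeneracies through rounding noise, narrow enough that a 1e-6 joggle
  // moves configurations well clear of it.
  const double diam2 = diam * diam;

  List degen = List::create(_["simplices"] = IntegerMatrix(0, 4),
                            _["degenerate"] = true);

  // Initial non-degenerate tetrahedron: greedy max-extent choice.
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  {
    double best = -1.0;
    for (int i = 1; i < n; ++i) {
      double d = 0.0;
      for (int j = 0; j < 3; ++j)
        d += (pts[i][j] - pts[i0][j]) * (pts[i][j] - pts[i0][j]);
      if (d > best) { best = d; i1 = i; }
    }
    if (best <= 0.0) return degen;
    best = -1.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1) continue;
      double u[3], v[3], cx[3];
      for (int j = 0; j < 3; ++j) {
        u[j] = pts[i1][j] - pts[i0][j];
        v[j] = pts[i][j] - pts[i0][j];
      }
      cx[0] = u[1] * v[2] - u[2] * v[1];
      cx[1] = u[2] * v[0] - u[0] * v[2];
      cx[2] = u[0] * v[1] - u[1] * v[0];
      double a2 = cx[0] * cx[0] + cx[1] * cx[1] + cx[2] * cx[2];
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (i2 < 0 || best <= 0.0) return degen;
    best = -1.0;
    double sc, keep = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2) continue;
      double o = orient3d(pts[i0], pts[i1], pts[i2], pts[i], sc);
      if (std::fabs(o) > best) { best = std::fabs(o); i3 = i; keep = sc; }
    }
    if (i3 < 0 || best <= tol_flat * keep * keep * keep) return degen;
  }

  std::array<double, 3> O;  // interior reference point of the (convex) hull
  for (int j = 0; j < 3; ++j)
    O[j] = 0.25 * (pts[i0][j] + pts[i1][j] + pts[i2][j] + pts[i3][j]);

  std::vector<Tet> tets;
  tets.reserve(8 * (size_t)n);
  {
    Tet t;
    t.v[0] = i0; t.v[1] = i1; t.v[2] = i2; t.v[3] = i3;
    if (!circumsphere(pts, t.v, t.cc, t.r2, tol_flat)) return degen;
    t.alive = true;
    tets.push_back(t);
    const int f[4][3] = {{i1, i2, i3}, {i0, i2, i3}, {i0, i1, i3}, {i0, i1, i2}};
    for (int k = 0; k < 4; ++k) {
      Tet ti;
      ti.v[0] = f[k][0]; ti.v[1] = f[k][1]; ti.v[2] = f[k][2]; ti.v[3] = INF;
      ti.r2 = 0.0; ti.cc[0] = ti.cc[1] = ti.cc[2] = 0.0;
      ti.alive = true;
      tets.push_back(ti);
    }
  }

  std::vector<int> bad;
  typedef std::array<int, 3> Facet;

  for (int ip = 0; ip < n; ++ip) {
    if (ip == i0 || ip == i1 || ip == i2 || ip == i3) continue;
    const std::array<double, 3>& p = pts[ip];
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      if (is_infinite(tets[t])) {
        double sc;
        double op = orient3d(pts[tets[t].v[0]], pts[tets[t].v[1]],
                             pts[tets[t].v[2]], p, sc);
        double sc2;
        double oo = orient3d(pts[tets[t].v[0]], pts[tets[t].v[1]],
                             pts[tets[t].v[2]], O, sc2);
        double band = tol_flat * sc * sc * sc;
        double band2 = tol_flat * sc2 * sc2 * sc2;
        if (std::fabs(oo) <= band2) return degen;
        if (std::fabs(op) <= band) {
          // p coplanar with the hull facet: the symbolic rule decides by the
          // in-circumcircle test within the facet plane
          double c2[3], rr2;
          if (!circumcircle3d(pts[tets[t].v[0]], pts[tets[t].v[1]],
                              pts[tets[t].v[2]], c2, rr2)) {
            // circumcircle3d computes from the first three points; a failure
            // means the facet itself is (nearly) collinear
            return degen;
          }
          double e0 = p[0] - c2[0], e1 = p[1] - c2[1], e2 = p[2] - c2[2];
          double dd = e0 * e0 + e1 * e1 + e2 * e2 - rr2;
          double band3 = 1e-11 * std::max(diam2, rr2);
          // on-circle counts as conflict (symbolic sphere inflation); a
          // genuinely inconsistent cavity surfaces as a flat new cell below
          if (dd < band3) bad.push_back((int)t);
        } else if (op * oo < 0) {
          bad.push_back((int)t);  // p strictly beyond this hull facet
        }
      } else {
        double d0 = p[0] - tets[t].cc[0];
        double d1 = p[1] - tets[t].cc[1];
        double d2 = p[2] - tets[t].cc[2];
        double d = d0 * d0 + d1 * d1 + d2 * d2 - tets[t].r2;
        double band = 1e-11 * std::max(diam2, tets[t].r2);
        // on-sphere counts as conflict (symbolic sphere inflation)
        if (d < band) bad.push_back((int)t);
      }
    }
    if (bad.empty()) return degen;  // duplicate point or numerical trouble

    std::map<Facet, int> fcount;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      const Tet& t = tets[bad[bi]];
      for (int skip = 0; skip < 4; ++skip) {
        Facet f;
        int k = 0;
        for (int j = 0; j < 4; ++j) if (j != skip) f[k++] = t.v[j];
        std::sort(f.begin(), f.end());  // INF (= -1) sorts first
        fcount[f]++;
      }
      tets[bad[bi]].alive = false;
    }
    for (std::map<Facet, int>::const_iterator it = fcount.begin();
         it != fcount.end(); ++it) {
      if (it->second != 1) continue;
      const Facet& f = it->first;
      Tet nt;
      if (f[0] == INF) {  // boundary facet through infinity -> new hull cell
        nt.v[0] = f[1]; nt.v[1] = f[2]; nt.v[2] = ip; nt.v[3] = INF;
        nt.r2 = 0.0; nt.cc[0] = nt.cc[1] = nt.cc[2] = 0.0;
      } else {
        nt.v[0] = f[0]; nt.v[1] = f[1]; nt.v[2] = f[2]; nt.v[3] = ip;
        if (!circumsphere(pts, nt.v, nt.cc, nt.r2, tol_flat)) return degen;
      }
      nt.alive = true;
      tets.push_back(nt);
    }
  }

  std::vector<std::array<int, 4>> keep;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive || is_infinite(tets[t])) continue;
    std::array<int, 4> s = { tets[t].v[0], tets[t].v[1],
                             tets[t].v[2], tets[t].v[3] };
    std::sort(s.begin(), s.end());
    keep.push_back(s);
  }
  std::sort(keep.begin(), keep.end());

  // Validity certificate: the finite cells must form a 2-manifold-bounded
  // complex (every facet in at most two cells) whose total volume equals the
  // volume enclosed by its boundary facets (divergence theorem).  Near-
  // degenerate inputs that slipped through the predicate bands with an
  // inconsistent cavity fail here and are reported as degenerate, so the
  // caller can joggle and retry.
  {
    std::map<Facet, std::vector<int>> fmap;
    double volsum = 0.0;
    for (size_t i = 0; i < keep.size(); ++i) {
      double sc;
      double o6 = orient3d(pts[keep[i][0]], pts[keep[i][1]],
                           pts[keep[i][2]], pts[keep[i][3]], sc);
      volsum += std::fabs(o6) / 6.0;
      const int combs[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
      for (int k = 0; k < 4; ++k) {
        Facet f = { keep[i][combs[k][0]], keep[i][combs[k][1]],
                    keep[i][combs[k][2]] };
        fmap[f].push_back((int)i);
      }
    }
    double bvol = 0.0;
    for (std::map<Facet, std::vector<int>>::const_iterator it = fmap.begin();
         it != fmap.end(); ++it) {
      if (it->second.size() > 2) return degen;
      if (it->second.size() != 1) continue;
      const Facet& f = it->first;
      const std::array<int, 4>& cell = keep[it->second[0]];
      int opp = -1;
      for (int j = 0; j < 4; ++j) {
        if (cell[j] != f[0] && cell[j] != f[1] && cell[j] != f[2])
          opp = cell[j];
      }
      const std::array<double, 3>& a = pts[f[0]];
      const std::array<double, 3>& b = pts[f[1]];
      const std::array<double, 3>& c = pts[f[2]];
      double sc;
      double side = orient3d(a, b, c, pts[opp], sc);
      double tri = (a[0] * (b[1] * c[2] - b[2] * c[1])
                  - a[1] * (b[0] * c[2] - b[2] * c[0])
                  + a[2] * (b[0] * c[1] - b[1] * c[0])) / 6.0;
      bvol += (side > 0) ? -tri : tri;
    }
    if (std::fabs(std::fabs(bvol) - volsum) >
        1e-8 * std::max(1.0, volsum)) return degen;
  }

  IntegerMatrix out((int)keep.size(), 4);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int j = 0; j < 4; ++j) out((int)i, j) = keep[i][j] + 1;  // 1-based
  return List::create(_["simplices"] = out, _["degenerate"] = false);
}
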