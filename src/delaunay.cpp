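// Incremental Bowyer-Watson Delaunay tessellation (3D and 2D).
// 3D uses visibility walking + cavity breadth-first search over a tet
// adjacency structure (amortized ~O(1) per insertion); 2D uses a simple
// linear cavity scan (point counts there are small). Degenerate
// (cospherical) inputs are expected to be jittered by the R caller before
// tessellation; the simplex list is topology only, all metric quantities
// (volumes, areas, circumradii for the alpha filter) are recomputed in R
// from the original unjittered coordinates.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::array<double,3> P3;

struct Tet {
  int v[4];
  int nbr[4];     // neighbour through the face opposite v[k]; -1 = none
  double cc[3];
  double r2;
  bool alive;
};

bool tet_circum(const std::vector<P3> &P, const int v[4], double cc[3],
                double &r2) {
  const P3 &a = P[v[0]];
  double A[3][3], b[3];
  for (int k = 1; k < 4; ++k) {
    double dx = P[v[k]][0] - a[0], dy = P[v[k]][1] - a[1], dz = P[v[k]][2] - a[2];
    A[k-1][0] = 2.0 * dx; A[k-1][1] = 2.0 * dy; A[k-1][2] = 2.0 * dz;
    b[k-1] = dx*dx + dy*dy + dz*dz;
  }
  double det =
      A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
    - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
    + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  double scale = 0.0;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) scale = std::max(scale, std::fabs(A[r][c]));
  if (std::fabs(det) < 1e-12 * scale * scale * scale) return false;
  double x =
      (b[0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
     - A[0][1]*(b[1]*A[2][2]-A[1][2]*b[2])
     + A[0][2]*(b[1]*A[2][1]-A[1][1]*b[2])) / det;
  double y =
      (A[0][0]*(b[1]*A[2][2]-A[1][2]*b[2])
     - b[0]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
     + A[0][2]*(A[1][0]*b[2]-b[1]*A[2][0])) / det;
  double z =
      (A[0][0]*(A[1][1]*b[2]-b[1]*A[2][1])
     - A[0][1]*(A[1][0]*b[2]-b[1]*A[2][0])
     + b[0]*(A[1][0]*A[2][1]-A[1][1]*A[2][0])) / det;
  cc[0] = a[0] + x; cc[1] = a[1] + y; cc[2] = a[2] + z;
  r2 = x*x + y*y + z*z;
  return true;
}

inline double orient(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  double b0 = b[0]-a[0], b1 = b[1]-a[1], b2 = b[2]-a[2];
  double c0 = c[0]-a[0], c1 = c[1]-a[1], c2 = c[2]-a[2];
  double d0 = d[0]-a[0], d1 = d[1]-a[1], d2 = d[2]-a[2];
  return b0*(c1*d2-c2*d1) - b1*(c0*d2-c2*d0) + b2*(c0*d1-c1*d0);
}

inline bool in_sphere(const Tet &t, const P3 &p) {
  if (!std::isfinite(t.r2)) return true;
  double dx = p[0]-t.cc[0], dy = p[1]-t.cc[1], dz = p[2]-t.cc[2];
  return dx*dx + dy*dy + dz*dz < t.r2 * (1.0 + 1e-12);
}

struct Tri {
  int v[3];
  double cc[2];
  double r2;
  bool alive;
};

bool tri_circum(const std::vector<std::array<double,2> > &P, const int v[3],
                double cc[2], double &r2) {
  const std::array<double,2> &a = P[v[0]];
  double A[2][2], b[2];
  for (int k = 1; k < 3; ++k) {
    double dx = P[v[k]][0] - a[0], dy = P[v[k]][1] - a[1];
    A[k-1][0] = 2.0 * dx; A[k-1][1] = 2.0 * dy;
    b[k-1] = dx*dx + dy*dy;
  }
  double det = A[0][0]*A[1][1] - A[0][1]*A[1][0];
  double scale = std::max(std::max(std::fabs(A[0][0]), std::fabs(A[0][1])),
                          std::max(std::fabs(A[1][0]), std::fabs(A[1][1])));
  if (std::fabs(det) < 1e-12 * scale * scale) return false;
  double x = (b[0]*A[1][1] - A[0][1]*b[1]) / det;
  double y = (A[0][0]*b[1] - b[0]*A[1][0]) / det;
  cc[0] = a[0] + x; cc[1] = a[1] + y;
  r2 = x*x + y*y;
  return true;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<P3> P(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      P[i][d] = pts(i, d);
      lo[d] = std::min(lo[d], P[i][d]);
      hi[d] = std::max(hi[d], P[i][d]);
    }
  }
  double cx = 0.5*(lo[0]+hi[0]), cy = 0.5*(lo[1]+hi[1]), cz = 0.5*(lo[2]+hi[2]);
  double diam = std::max(1e-8, std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                   (hi[1]-lo[1])*(hi[1]-lo[1]) + (hi[2]-lo[2])*(hi[2]-lo[2])));
  double R = 50.0 * diam;
  P[n]     = { cx + R, cy + R, cz + R };
  P[n + 1] = { cx + R, cy - R, cz - R };
  P[n + 2] = { cx - R, cy + R, cz - R };
  P[n + 3] = { cx - R, cy - R, cz + R };

  std::vector<Tet> T;
  T.reserve(12 * n + 64);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n+1; t0.v[2] = n+2; t0.v[3] = n+3;
    t0.nbr[0] = t0.nbr[1] = t0.nbr[2] = t0.nbr[3] = -1;
    if (!tet_circum(P, t0.v, t0.cc, t0.r2)) stop("degenerate super-tetrahedron");
    t0.alive = true;
    T.push_back(t0);
  }
  int last_tet = 0;

  std::vector<int> cavity, stack;
  std::vector<int> stamp;      // epoch*2 = cavity, epoch*2+1 = visited
  stamp.reserve(12 * n + 64);
  int epoch = 0;

  for (int ip = 0; ip < n; ++ip) {
    const P3 &p = P[ip];

    // --- locate a first bad tetrahedron: visibility walk, fallback scan ---
    int seed = -1;
    int cur = last_tet;
    if (cur < 0 || cur >= (int)T.size() || !T[cur].alive) {
      for (int k = (int)T.size() - 1; k >= 0; --k)
        if (T[k].alive) { cur = k; break; }
    }
    for (int steps = 0; steps < 4 * (int)T.size() + 16; ++steps) {
      const Tet &t = T[cur];
      int move = -1;
      for (int f = 0; f < 4; ++f) {
        int a = t.v[(f+1)&3], b = t.v[(f+2)&3], c = t.v[(f+3)&3];
        double op = orient(P[a], P[b], P[c], p);
        double ov = orient(P[a], P[b], P[c], P[t.v[f]]);
        if (op * ov < -1e-300 && std::fabs(op) > 1e-18 * std::fabs(ov) ) {
          if (t.nbr[f] >= 0 && T[t.nbr[f]].alive) { move = t.nbr[f]; break; }
        }
      }
      if (move < 0) { seed = cur; break; }
      cur = move;
    }
    if (seed < 0 || !in_sphere(T[seed], p)) {
      seed = -1;
      for (int k = (int)T.size() - 1; k >= 0; --k)
        if (T[k].alive && in_sphere(T[k], p)) { seed = k; break; }
      if (seed < 0) stop("tessellation failure: point outside all circumspheres");
    }

    // --- cavity BFS over adjacency (epoch stamps avoid O(T) clears) ---
    if (stamp.size() < T.size()) stamp.resize(T.size() + 1024, -1);
    ++epoch;
    const int IN_CAV = 2 * epoch, SEEN = 2 * epoch + 1;
    cavity.clear(); stack.clear();
    stack.push_back(seed); stamp[seed] = IN_CAV; cavity.push_back(seed);
    std::vector<std::array<int,4> > bfaces;  // {a,b,c, outside tet (-1 none)}
    std::vector<int> boutf;                  // face index in outside tet
    while (!stack.empty()) {
      int tcur = stack.back(); stack.pop_back();
      const Tet &t = T[tcur];
      for (int f = 0; f < 4; ++f) {
        int nb = t.nbr[f];
        int a = t.v[(f+1)&3], b = t.v[(f+2)&3], c = t.v[(f+3)&3];
        if (nb >= 0 && T[nb].alive) {
          if (stamp[nb] == IN_CAV) continue;
          if (stamp[nb] != SEEN && in_sphere(T[nb], p)) {
            stamp[nb] = IN_CAV; cavity.push_back(nb); stack.push_back(nb);
          } else {
            stamp[nb] = SEEN;
            int g = 0;
            for (; g < 4; ++g) if (T[nb].nbr[g] == tcur) break;
            bfaces.push_back({a, b, c, nb});
            boutf.push_back(g < 4 ? g : -1);
          }
        } else {
          bfaces.push_back({a, b, c, -1});
          boutf.push_back(-1);
        }
      }
    }
    for (size_t k = 0; k < cavity.size(); ++k) T[cavity[k]].alive = false;

    // --- retriangulate: one new tet per boundary face ---
    std::map<std::pair<int,int>, std::pair<int,int> > edge2tet;
    int first_new = (int)T.size();
    for (size_t f = 0; f < bfaces.size(); ++f) {
      Tet nt;
      nt.v[0] = bfaces[f][0]; nt.v[1] = bfaces[f][1]; nt.v[2] = bfaces[f][2];
      nt.v[3] = ip;
      nt.nbr[0] = nt.nbr[1] = nt.nbr[2] = nt.nbr[3] = -1;
      if (!tet_circum(P, nt.v, nt.cc, nt.r2)) {
        nt.cc[0] = nt.cc[1] = nt.cc[2] = 0.0;
        nt.r2 = R_PosInf;          // flat sliver: destroyed on next contact
      }
      nt.alive = true;
      int id = (int)T.size();
      // face opposite ip (index 3) borders the outside tet
      nt.nbr[3] = bfaces[f][3];
      if (bfaces[f][3] >= 0 && boutf[f] >= 0)
        T[bfaces[f][3]].nbr[boutf[f]] = id;
      T.push_back(nt);
      // faces containing ip: share an edge of the boundary face
      static const int E[3][2] = {{1,2},{0,2},{0,1}};
      for (int e = 0; e < 3; ++e) {
        int u = T[id].v[E[e][0]], w = T[id].v[E[e][1]];
        std::pair<int,int> key(std::min(u,w), std::max(u,w));
        std::map<std::pair<int,int>, std::pair<int,int> >::iterator it =
          edge2tet.find(key);
        if (it == edge2tet.end()) {
          edge2tet[key] = std::make_pair(id, e);
        } else {
          int other = it->second.first, of = it->second.second;
          T[id].nbr[e] = other;        // face opposite v[e] contains ip+edge
          T[other].nbr[of] = id;
        }
      }
    }
    last_tet = first_new < (int)T.size() ? first_new : last_tet;
    if (T.size() > 4e7) stop("tessellation exploded; input too degenerate");
  }

  int m = 0;
  for (size_t k = 0; k < T.size(); ++k) {
    if (!T[k].alive) continue;
    if (T[k].v[0] < n && T[k].v[1] < n && T[k].v[2] < n && T[k].v[3] < n) ++m;
  }
  IntegerMatrix out(m, 4);
  int r = 0;
  for (size_t k = 0; k < T.size(); ++k) {
    if (!T[k].alive) continue;
    if (T[k].v[0] >= n || T[k].v[1] >= n || T[k].v[2] >= n || T[k].v[3] >= n)
      continue;
    for (int d = 0; d < 4; ++d) out(r, d) = T[k].v[d] + 1;
    ++r;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".delaunay2d_cpp")]]
IntegerMatrix delaunay2d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<std::array<double,2> > P(n + 3);
  double lo[2] = {R_PosInf, R_PosInf}, hi[2] = {R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 2; ++d) {
      P[i][d] = pts(i, d);
      lo[d] = std::min(lo[d], P[i][d]);
      hi[d] = std::max(hi[d], P[i][d]);
    }
  }
  double cx = 0.5*(lo[0]+hi[0]), cy = 0.5*(lo[1]+hi[1]);
  double diam = std::max(1e-8, std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                                         (hi[1]-lo[1])*(hi[1]-lo[1])));
  double R = 50.0 * diam;
  P[n]     = { cx,           cy + 2.0*R };
  P[n + 1] = { cx + 1.8*R,   cy - R     };
  P[n + 2] = { cx - 1.8*R,   cy - R     };

  std::vector<Tri> tris;
  tris.reserve(4 * n + 32);
  {
    Tri t0; t0.v[0] = n; t0.v[1] = n+1; t0.v[2] = n+2;
    if (!tri_circum(P, t0.v, t0.cc, t0.r2)) stop("degenerate super-triangle");
    t0.alive = true;
    tris.push_back(t0);
  }

  std::vector<int> bad;
  typedef std::array<int,2> Edge;
  std::map<Edge, int> edgeCount;
  std::vector<Edge> edges;

  for (int ip = 0; ip < n; ++ip) {
    const std::array<double,2> &p = P[ip];
    bad.clear();
    for (size_t k = 0; k < tris.size(); ++k) {
      if (!tris[k].alive) continue;
      if (!std::isfinite(tris[k].r2)) { bad.push_back((int)k); continue; }
      double dx = p[0]-tris[k].cc[0], dy = p[1]-tris[k].cc[1];
      if (dx*dx + dy*dy < tris[k].r2 * (1.0 + 1e-12)) bad.push_back((int)k);
    }
    if (bad.empty()) stop("tessellation failure: point outside all circumcircles");
    edgeCount.clear();
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tri &t = tris[bad[b]];
      static const int E[3][2] = {{0,1},{0,2},{1,2}};
      for (int e = 0; e < 3; ++e) {
        Edge eg = { t.v[E[e][0]], t.v[E[e][1]] };
        if (eg[0] > eg[1]) std::swap(eg[0], eg[1]);
        edgeCount[eg]++;
      }
      tris[bad[b]].alive = false;
    }
    edges.clear();
    for (std::map<Edge,int>::const_iterator it = edgeCount.begin();
         it != edgeCount.end(); ++it)
      if (it->second == 1) edges.push_back(it->first);
    for (size_t e = 0; e < edges.size(); ++e) {
      Tri nt;
      nt.v[0] = edges[e][0]; nt.v[1] = edges[e][1]; nt.v[2] = ip;
      if (!tri_circum(P, nt.v, nt.cc, nt.r2)) {
        nt.cc[0] = nt.cc[1] = 0.0;
        nt.r2 = R_PosInf;
      }
      nt.alive = true;
      tris.push_back(nt);
    }
  }

  int m = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (!tris[k].alive) continue;
    if (tris[k].v[0] < n && tris[k].v[1] < n && tris[k].v[2] < n) ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (!tris[k].alive) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    for (int d = 0; d < 3; ++d) out(r, d) = tris[k].v[d] + 1;
    ++r;
  }
  return out;
}
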