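// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson) with the
// circumradius filter used for alpha-shape volume estimation.
//
// The build runs on coordinates scaled into the unit box and symbolically
// jittered (fixed LCG stream) so cospherical/coplanar inputs resolve to a
// consistent combinatorial structure; tetrahedron volumes are evaluated on
// the ORIGINAL coordinates so the hull-limit volume is exact for degenerate
// inputs, while circumradii come from the jittered coordinates (always
// finite for non-degenerate jittered tetrahedra).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];      // vertex ids (0..3 are the super-tetrahedron)
  int adj[4];    // neighbour opposite vertex i, -1 if none
  bool alive;
  double cc[3];  // circumcenter (scaled coords)
  double r2;     // squared circumradius (scaled coords)
};

inline double orient3d(const double* a, const double* b, const double* c,
                       const double* d) {
  double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

// circumcenter of tetrahedron by Cramer solve; returns false if degenerate
inline bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double* cc, double& r2) {
  double A[3][3], rhs[3];
  const double* pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    rhs[i] = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (pts[i][j] - a[j]);
      rhs[i] += pts[i][j] * pts[i][j] - a[j] * a[j];
    }
  }
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double inv = 1.0 / det;
  cc[0] = inv * (rhs[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                 A[0][1] * (rhs[1] * A[2][2] - A[1][2] * rhs[2]) +
                 A[0][2] * (rhs[1] * A[2][1] - A[1][1] * rhs[2]));
  cc[1] = inv * (A[0][0] * (rhs[1] * A[2][2] - A[1][2] * rhs[2]) -
                 rhs[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                 A[0][2] * (A[1][0] * rhs[2] - rhs[1] * A[2][0]));
  cc[2] = inv * (A[0][0] * (A[1][1] * rhs[2] - rhs[1] * A[2][1]) -
                 A[0][1] * (A[1][0] * rhs[2] - rhs[1] * A[2][0]) +
                 rhs[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]));
  double dx = cc[0] - a[0], dy = cc[1] - a[1], dz = cc[2] - a[2];
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

struct Triangulator {
  std::vector<std::array<double, 3>> pts;  // scaled+jittered, 0..3 super
  std::vector<Tet> tets;
  std::vector<int> free_list;
  std::vector<int> mark;  // epoch marks: per-insert visited flags in O(1)
  int epoch = 0;
  int last_tet = 0;
  bool failed = false;

  const double* P(int i) const { return pts[(size_t)i].data(); }

  int new_tet(int a, int b, int c, int d) {
    Tet t;
    // enforce positive orientation
    if (orient3d(P(a), P(b), P(c), P(d)) < 0) std::swap(c, d);
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.adj[0] = t.adj[1] = t.adj[2] = t.adj[3] = -1;
    t.alive = true;
    if (!circumsphere(P(t.v[0]), P(t.v[1]), P(t.v[2]), P(t.v[3]), t.cc, t.r2)) {
      failed = true;
      t.r2 = -1.0;  // degenerate: conflicts with nothing
    }
    int id;
    if (!free_list.empty()) {
      id = free_list.back(); free_list.pop_back();
      tets[(size_t)id] = t;
    } else {
      id = (int)tets.size();
      tets.push_back(t);
    }
    return id;
  }

  inline bool in_sphere(const Tet& t, const double* p) const {
    if (t.r2 < 0) return false;
    double dx = p[0] - t.cc[0], dy = p[1] - t.cc[1], dz = p[2] - t.cc[2];
    return dx * dx + dy * dy + dz * dz < t.r2;
  }

  // walk to a tetrahedron containing p
  int locate(const double* p) {
    int cur = last_tet;
    if (!tets[(size_t)cur].alive) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[(size_t)i].alive) { cur = i; break; }
      if (cur < 0) return -1;
    }
    size_t guard = tets.size() * 4 + 64;
    for (size_t step = 0; step < guard; ++step) {
      const Tet& t = tets[(size_t)cur];
      int next = -1;
      for (int f = 0; f < 4; ++f) {
        // face opposite vertex f; p outside that face plane?
        const int* v = t.v;
        int a = v[(f + 1) & 3], b = v[(f + 2) & 3], c = v[(f + 3) & 3];
        double o_p = orient3d(P(a), P(b), P(c), p);
        double o_v = orient3d(P(a), P(b), P(c), P(v[f]));
        if (o_p * o_v < 0) {  // p on the far side
          if (t.adj[f] >= 0) { next = t.adj[f]; break; }
        }
      }
      if (next < 0) return cur;
      cur = next;
    }
    // walk cycled (numerical trouble): brute-force scan by circumsphere
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[(size_t)i].alive && in_sphere(tets[(size_t)i], p)) return i;
    return -1;
  }

  bool insert(int pid) {
    const double* p = P(pid);
    int seed_tet = locate(p);
    if (seed_tet < 0) return false;
    // conflict region BFS
    std::vector<int> cavity;
    if (mark.size() < tets.size()) mark.resize(tets.size() + 1024, 0);
    ++epoch;
    std::vector<int> stack{seed_tet};
    mark[(size_t)seed_tet] = epoch;
    if (!in_sphere(tets[(size_t)seed_tet], p)) {
      // containing tet should conflict; if predicate disagrees, fail over
      // by accepting it anyway (keeps the cavity non-empty and star-shaped)
    }
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      cavity.push_back(id);
      for (int f = 0; f < 4; ++f) {
        int nb = tets[(size_t)id].adj[f];
        if (nb >= 0 && mark[(size_t)nb] != epoch && tets[(size_t)nb].alive &&
            in_sphere(tets[(size_t)nb], p)) {
          mark[(size_t)nb] = epoch;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces: (3 vertices, outside neighbour, its face index)
    struct BFace { int a, b, c, nb; };
    std::vector<BFace> bfaces;
    for (int id : cavity) {
      const Tet& t = tets[(size_t)id];
      for (int f = 0; f < 4; ++f) {
        int nb = t.adj[f];
        bool nb_in_cavity = nb >= 0 && mark[(size_t)nb] == epoch &&
                            tets[(size_t)nb].alive;
        if (nb_in_cavity) continue;
        bfaces.push_back({t.v[(f + 1) & 3], t.v[(f + 2) & 3],
                          t.v[(f + 3) & 3], nb});
      }
    }
    for (int id : cavity) { tets[(size_t)id].alive = false; free_list.push_back(id); }
    // build new tets, stitch adjacency
    std::map<std::pair<int, int>, std::pair<int, int>> half_face;  // edge->tet,face
    int first_new = -1;
    for (const BFace& bf : bfaces) {
      int id = new_tet(pid, bf.a, bf.b, bf.c);
      Tet& t = tets[(size_t)id];
      // locate which local face is opposite pid (pid is v[k] for some k)
      int kp = -1;
      for (int k = 0; k < 4; ++k) if (t.v[k] == pid) kp = k;
      t.adj[kp] = bf.nb;
      if (bf.nb >= 0) {
        Tet& n = tets[(size_t)bf.nb];
        // neighbour's face made of {a,b,c}: the face not containing any
        // cavity vertex — identify by matching vertex sets
        for (int f = 0; f < 4; ++f) {
          int x = n.v[(f + 1) & 3], y = n.v[(f + 2) & 3], z = n.v[(f + 3) & 3];
          int match = 0;
          for (int w : {x, y, z})
            if (w == bf.a || w == bf.b || w == bf.c) ++match;
          if (match == 3) { n.adj[f] = id; break; }
        }
      }
      // internal faces contain pid + one edge of the boundary triangle
      int tri[3] = {bf.a, bf.b, bf.c};
      for (int e = 0; e < 3; ++e) {
        int u = tri[e], w = tri[(e + 1) % 3];
        if (u > w) std::swap(u, w);
        auto key = std::make_pair(u, w);
        auto it = half_face.find(key);
        // local face of t opposite the third triangle vertex
        int third = tri[(e + 2) % 3];
        int kf = -1;
        for (int k = 0; k < 4; ++k) if (t.v[k] == third) kf = k;
        if (it == half_face.end()) {
          half_face[key] = std::make_pair(id, kf);
        } else {
          int oid = it->second.first, of = it->second.second;
          tets[(size_t)id].adj[kf] = oid;
          tets[(size_t)oid].adj[of] = id;
          half_face.erase(it);
        }
      }
      if (first_new < 0) first_new = id;
    }
    if (!half_face.empty()) failed = true;  // cavity was not watertight
    if (first_new >= 0) last_tet = first_new;
    return first_new >= 0;
  }
};

// deterministic uniform stream for jitter and shuffling
struct LCG {
  uint64_t s;
  explicit LCG(uint64_t seed) : s(seed * 2862933555777941757ULL + 3037000493ULL) {}
  double next() {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return (double)(s >> 11) * (1.0 / 9007199254740992.0);
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay3d")]]
List delaunay3d_cpp(NumericMatrix coords, int seed = 1, double jitter = 1e-9) {
  const int n = coords.nrow();
  if (n < 4) stop("need at least 4 points for a tetrahedralization");

  // scale into unit box
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) {
    lo[j] = R_PosInf; hi[j] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = coords(i, j);
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  }
  double extent = 0.0;
  for (int j = 0; j < 3; ++j) extent = std::max(extent, hi[j] - lo[j]);
  if (extent <= 0) stop("degenerate input: all points coincide");

  for (int attempt = 0; attempt < 3; ++attempt) {
    double jit = jitter * std::pow(100.0, attempt);
    LCG rng((uint64_t)seed + 7919ULL * (uint64_t)attempt);

    Triangulator tri;
    tri.pts.resize((size_t)n + 4);
    const double L = 50.0;
    tri.pts[0] = {-L, -L, -L};
    tri.pts[1] = {3 * L, -L, -L};
    tri.pts[2] = {-L, 3 * L, -L};
    tri.pts[3] = {-L, -L, 3 * L};
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 3; ++j)
        tri.pts[(size_t)i + 4][(size_t)j] =
            (coords(i, j) - lo[j]) / extent + jit * (rng.next() - 0.5);

    tri.tets.reserve((size_t)n * 8 + 16);
    tri.new_tet(0, 1, 2, 3);

    // randomized insertion order (deterministic shuffle)
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[(size_t)i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng.next() * (i + 1));
      if (j > i) j = i;
      std::swap(order[(size_t)i], order[(size_t)j]);
    }

    bool ok = true;
    for (int i = 0; i < n && ok; ++i) ok = tri.insert(order[(size_t)i] + 4);
    if (!ok || tri.failed) continue;  // retry with larger jitter

    // collect finite tetrahedra; volumes on ORIGINAL coords
    std::vector<int> keep;
    for (int i = 0; i < (int)tri.tets.size(); ++i) {
      const Tet& t = tri.tets[(size_t)i];
      if (!t.alive) continue;
      if (t.v[0] < 4 || t.v[1] < 4 || t.v[2] < 4 || t.v[3] < 4) continue;
      keep.push_back(i);
    }
    int m = (int)keep.size();
    IntegerMatrix verts(m, 4);
    NumericVector vol(m), circ(m);
    for (int k = 0; k < m; ++k) {
      const Tet& t = tri.tets[(size_t)keep[(size_t)k]];
      double orig[4][3];
      for (int a = 0; a < 4; ++a) {
        int vid = t.v[a] - 4;
        verts(k, a) = vid + 1;  // 1-based
        for (int j = 0; j < 3; ++j) orig[a][j] = coords(vid, j);
      }
      // signed volume in build orientation; degenerate originals give ~0
      vol[k] = orient3d(orig[0], orig[1], orig[2], orig[3]) / 6.0;
      circ[k] = std::sqrt(std::max(t.r2, 0.0)) * extent;  // back to input units
    }
    return List::create(_["vertices"] = verts, _["volume"] = vol,
                        _["circumradius"] = circ, _["n_points"] = n,
                        _["jitter_attempt"] = attempt);
  }
  stop("tetrahedralization failed after jitter escalation (degenerate input)");
}
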