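// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralisation with a single
// symbolic vertex at infinity ("ghost" tetrahedra over the hull faces), so
// the finite tetrahedra tile the convex hull exactly.
//
// Plain double predicates with a deterministic-jitter restart when a
// degeneracy (cospherical/coplanar input) produces an inconsistent cavity:
// structured clouds (grids, spheres) take the jitter path, generic clouds
// are triangulated exactly as given.  Tetrahedra are reported on the
// original (unjittered) coordinates; circumradii are computed from those.

#include "geom.h"
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// defined in hull.cpp; used to validate each triangulation attempt
Rcpp::List C_convex_hull(Rcpp::NumericMatrix points);

namespace {

struct Tet {
  int v[4];
  int n[4];       // n[i]: neighbour opposite v[i], -1 if none
  bool alive;
  bool bad;       // scratch flag during cavity search
};

// sign < 0 iff e inside circumsphere of (a,b,c,d) when orient3d(a,b,c,d) > 0
double insphere(const V3& a, const V3& b, const V3& c, const V3& d, const V3& e) {
  V3 ae = a - e, be = b - e, ce = c - e, de = d - e;
  double al = dot(ae, ae), bl = dot(be, be), cl = dot(ce, ce), dl = dot(de, de);
  double ab = ae.x * be.y - be.x * ae.y;
  double bc = be.x * ce.y - ce.x * be.y;
  double cd = ce.x * de.y - de.x * ce.y;
  double da = de.x * ae.y - ae.x * de.y;
  double ac = ae.x * ce.y - ce.x * ae.y;
  double bd = be.x * de.y - de.x * be.y;
  double abc = ae.z * bc - be.z * ac + ce.z * ab;
  double bcd = be.z * cd - ce.z * bd + de.z * bc;
  double cda = ce.z * da + de.z * ac + ae.z * cd;
  double dab = de.z * ab + ae.z * bd + be.z * da;
  return dl * abc - cl * dab + bl * cda - al * bcd;
}

struct DT {
  std::vector<V3> pts;     // working (scaled, maybe jittered) coords
  int INF = -1;            // index of the symbolic infinite vertex
  V3 interior;             // a point interior to the hull (initial centroid)
  std::vector<Tet> tets;
  size_t max_tets = 0;   // growth cap; blown on degeneracy-corrupted runs
  int last_tet = 0;
  bool failed = false;

  bool is_ghost(const Tet& T) const {
    return T.v[0] == INF || T.v[1] == INF || T.v[2] == INF || T.v[3] == INF;
  }

  void ghost_face(const Tet& T, int f[3]) const {
    int k = 0;
    for (int i = 0; i < 4; ++i)
      if (T.v[i] != INF) f[k++] = T.v[i];
  }

  // "p inside circumsphere" (real) / "p beyond hull face" (ghost).  Plain
  // double signs; inconsistencies from near-zero predicates are caught by
  // the post-hoc hull-volume validation and resolved by a jitter restart.
  bool is_bad(const Tet& T, const V3& p) const {
    if (is_ghost(T)) {
      int f[3];
      ghost_face(T, f);
      double oc = orient3d(pts[f[0]], pts[f[1]], pts[f[2]], interior);
      double op = orient3d(pts[f[0]], pts[f[1]], pts[f[2]], p);
      return oc * op < 0;  // p strictly outside the hull face
    }
    double ow = orient3d(pts[T.v[0]], pts[T.v[1]], pts[T.v[2]], pts[T.v[3]]);
    double s = insphere(pts[T.v[0]], pts[T.v[1]], pts[T.v[2]], pts[T.v[3]], p);
    return (ow > 0 && s < 0) || (ow < 0 && s > 0);
  }

  bool point_in_tet(int t, const V3& p) const {
    const Tet& T = tets[t];
    if (is_ghost(T)) return false;
    for (int f = 0; f < 4; ++f) {
      const V3& x = pts[T.v[(f + 1) & 3]];
      const V3& y = pts[T.v[(f + 2) & 3]];
      const V3& z = pts[T.v[(f + 3) & 3]];
      double ow = orient3d(x, y, z, pts[T.v[f]]);
      double op = orient3d(x, y, z, p);
      if (ow * op < 0 && std::fabs(op) > 1e-14) return false;
    }
    return true;
  }

  // find a bad seed tet containing p (real) or a ghost p lies beyond
  int locate(const V3& p) {
    int cur = last_tet;
    if (cur < 0 || cur >= (int)tets.size() || !tets[cur].alive || is_ghost(tets[cur])) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive && !is_ghost(tets[i])) { cur = i; break; }
      if (cur < 0) return -1;
    }
    size_t steps = 0, max_steps = 8 * tets.size() + 64;
    while (steps++ < max_steps) {
      const Tet& T = tets[cur];
      int move_to = -2;
      for (int f = 0; f < 4; ++f) {
        const V3& x = pts[T.v[(f + 1) & 3]];
        const V3& y = pts[T.v[(f + 2) & 3]];
        const V3& z = pts[T.v[(f + 3) & 3]];
        double ow = orient3d(x, y, z, pts[T.v[f]]);
        double op = orient3d(x, y, z, p);
        if (ow > 0 ? (op < -1e-13) : (op > 1e-13)) { move_to = T.n[f]; break; }
      }
      if (move_to == -2) return cur;                    // inside this real tet
      if (move_to < 0 || !tets[move_to].alive) break;   // inconsistent
      if (is_ghost(tets[move_to])) {
        if (is_bad(tets[move_to], p)) return move_to;   // outside the hull here
        break;  // on/near the hull boundary: fall through to scan
      }
      cur = move_to;
    }
    // fallback: linear scan (real containment, then any bad ghost)
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && point_in_tet(i, p)) return i;
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && is_ghost(tets[i]) && is_bad(tets[i], p)) return i;
    return -1;
  }

  void insert(int ip) {
    const V3& p = pts[ip];
    if (tets.size() > max_tets) { failed = true; return; }
    int t0 = locate(p);
    if (t0 < 0 || failed) { failed = true; return; }
    if (!is_ghost(tets[t0]) && !is_bad(tets[t0], p)) {
      // p located in a tet but not strictly inside its circumsphere:
      // cospherical degeneracy or a mislocation from tolerance noise.
      // search the neighbourhood for a genuinely bad tet before giving up
      std::vector<int> ring{t0}, seen_{t0};
      int found = -1;
      for (size_t qi = 0; qi < ring.size() && qi < 64 && found < 0; ++qi) {
        for (int f = 0; f < 4 && found < 0; ++f) {
          int nb = tets[ring[qi]].n[f];
          if (nb < 0 || !tets[nb].alive) continue;
          bool dup = false;
          for (int s : seen_) if (s == nb) { dup = true; break; }
          if (dup) continue;
          seen_.push_back(nb);
          ring.push_back(nb);
          if (is_bad(tets[nb], p)) found = nb;
        }
      }
      if (found < 0) { failed = true; return; }
      t0 = found;
    }

    std::vector<int> bad, stack_;
    stack_.push_back(t0);
    tets[t0].bad = true;
    while (!stack_.empty()) {
      int t = stack_.back(); stack_.pop_back();
      bad.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].n[f];
        if (nb < 0 || !tets[nb].alive || tets[nb].bad) continue;
        if (is_bad(tets[nb], p)) {
          tets[nb].bad = true;
          stack_.push_back(nb);
        }
      }
    }
    if (failed) return;  // ambiguous predicate met during cavity search

    // cavity boundary faces (may contain INF); oriented arbitrarily, the
    // predicates re-derive orientation at test time
    struct BFace { int a, b, c, outside; };
    std::vector<BFace> bf;
    for (int t : bad) {
      for (int f = 0; f < 4; ++f) {
        int nb = tets[t].n[f];
        if (nb >= 0 && tets[nb].bad) continue;
        int a = tets[t].v[(f + 1) & 3];
        int b = tets[t].v[(f + 2) & 3];
        int c = tets[t].v[(f + 3) & 3];
        if (a != INF && b != INF && c != INF) {
          double o = orient3d(pts[a], pts[b], pts[c], p);
          if (o < 0) std::swap(b, c);
          o = orient3d(pts[a], pts[b], pts[c], p);
          if (o <= 0) { failed = true; return; }  // exactly flat: degenerate
        }
        bf.push_back({a, b, c, nb});
      }
    }
    for (int t : bad) { tets[t].alive = false; tets[t].bad = false; }

    std::unordered_map<uint64_t, std::pair<int, int>> open_face;
    int base = (int)tets.size();
    int first_real = -1;
    for (size_t i = 0; i < bf.size(); ++i) {
      Tet T;
      T.v[0] = ip; T.v[1] = bf[i].a; T.v[2] = bf[i].b; T.v[3] = bf[i].c;
      T.n[0] = bf[i].outside;
      T.n[1] = T.n[2] = T.n[3] = -1;
      T.alive = true; T.bad = false;
      int ti = base + (int)i;
      if (!is_ghost(T) && first_real < 0) first_real = ti;
      if (bf[i].outside >= 0) {
        Tet& O = tets[bf[i].outside];
        for (int f = 0; f < 4; ++f) {
          int x = O.v[(f + 1) & 3], y = O.v[(f + 2) & 3], z = O.v[(f + 3) & 3];
          if (x + y + z != bf[i].a + bf[i].b + bf[i].c) continue;
          bool match =
            (x == bf[i].a || x == bf[i].b || x == bf[i].c) &&
            (y == bf[i].a || y == bf[i].b || y == bf[i].c) &&
            (z == bf[i].a || z == bf[i].b || z == bf[i].c);
          if (match) { O.n[f] = ti; break; }
        }
      }
      tets.push_back(T);
      // internal faces all contain p; key by the two other vertices
      int vv[4] = {ip, bf[i].a, bf[i].b, bf[i].c};
      for (int f = 1; f < 4; ++f) {
        int idx[3];
        int k = 0;
        for (int g = 0; g < 4; ++g) if (g != f) idx[k++] = vv[g];
        int o1, o2;
        if (idx[0] == ip) { o1 = idx[1]; o2 = idx[2]; }
        else if (idx[1] == ip) { o1 = idx[0]; o2 = idx[2]; }
        else { o1 = idx[0]; o2 = idx[1]; }
        uint64_t key = o1 < o2 ? (uint64_t)(uint32_t)o1 << 32 | (uint32_t)o2
                               : (uint64_t)(uint32_t)o2 << 32 | (uint32_t)o1;
        auto it = open_face.find(key);
        if (it == open_face.end()) {
          open_face[key] = {ti, f};
        } else {
          tets[ti].n[f] = it->second.first;
          tets[it->second.first].n[it->second.second] = ti;
          open_face.erase(it);
        }
      }
    }
    if (!open_face.empty()) { failed = true; return; }
    if (first_real >= 0) last_tet = first_real;
  }
};

}  // namespace

// [[Rcpp::export(name = ".C_delaunay3d")]]
IntegerMatrix C_delaunay3d(NumericMatrix points, int seed) {
  int n = points.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<V3> orig = mat_to_pts(points);

  V3 lo(R_PosInf, R_PosInf, R_PosInf), hi(R_NegInf, R_NegInf, R_NegInf);
  for (auto& p : orig) {
    lo = V3(std::min(lo.x, p.x), std::min(lo.y, p.y), std::min(lo.z, p.z));
    hi = V3(std::max(hi.x, p.x), std::max(hi.y, p.y), std::max(hi.z, p.z));
  }
  double span = std::max({hi.x - lo.x, hi.y - lo.y, hi.z - lo.z, 1e-300});
  V3 ctr = (lo + hi) * 0.5;

  std::vector<int> order(n);
  const int max_attempts = 8;
  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    // fresh insertion order per attempt so retries are independent
    uint64_t rs = ((uint64_t)seed + 0x9e37ULL * attempt) * 2654435761ULL
                + 1442695040888963407ULL;
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(splitmix64(rs) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    DT dt;
    dt.pts.resize(n + 1);
    dt.INF = n;
    dt.max_tets = 200 * (size_t)n + 20000;
    uint64_t js = rs ^ (0xabcdef12345ULL * (attempt + 1));
    // geometrically growing deterministic jitter (unit-box scale)
    double jmag = attempt == 0 ? 0.0 : 1e-8 * std::pow(6.0, attempt - 1);
    for (int i = 0; i < n; ++i) {
      V3 p = (orig[i] - ctr) * (1.0 / span);
      if (jmag > 0) {
        uint64_t s2 = js ^ ((uint64_t)i * 0x9e3779b97f4a7c15ULL);
        p.x += (unit_rand(s2) - 0.5) * jmag;
        p.y += (unit_rand(s2) - 0.5) * jmag;
        p.z += (unit_rand(s2) - 0.5) * jmag;
      }
      dt.pts[i] = p;
    }
    dt.pts[n] = V3(0, 0, 0);  // coordinates of INF are never used

    // initial simplex: first four affinely independent points in order
    int s0 = order[0], s1 = -1, s2 = -1, s3 = -1;
    int pos1 = -1, pos2 = -1, pos3 = -1;
    for (int i = 1; i < n && s1 < 0; ++i) {
      V3 d = dt.pts[order[i]] - dt.pts[s0];
      if (dot(d, d) > 1e-24) { s1 = order[i]; pos1 = i; }
    }
    for (int i = 1; i < n && s1 >= 0 && s2 < 0; ++i) {
      if (i == pos1) continue;
      V3 c = cross(dt.pts[s1] - dt.pts[s0], dt.pts[order[i]] - dt.pts[s0]);
      if (dot(c, c) > 1e-24) { s2 = order[i]; pos2 = i; }
    }
    for (int i = 1; i < n && s2 >= 0 && s3 < 0; ++i) {
      if (i == pos1 || i == pos2) continue;
      double o = orient3d(dt.pts[s0], dt.pts[s1], dt.pts[s2], dt.pts[order[i]]);
      if (std::fabs(o) > 1e-14) { s3 = order[i]; pos3 = i; }
    }
    if (s3 < 0) {
      if (attempt + 1 < max_attempts) continue;  // maybe jitter helps
      stop("degenerate (coplanar) point cloud");
    }
    if (orient3d(dt.pts[s0], dt.pts[s1], dt.pts[s2], dt.pts[s3]) < 0)
      std::swap(s2, s3);
    dt.interior = (dt.pts[s0] + dt.pts[s1] + dt.pts[s2] + dt.pts[s3]) * 0.25;

    // real tet 0 + four ghosts
    Tet T0;
    T0.v[0] = s0; T0.v[1] = s1; T0.v[2] = s2; T0.v[3] = s3;
    T0.alive = true; T0.bad = false;
    T0.n[0] = 1; T0.n[1] = 2; T0.n[2] = 3; T0.n[3] = 4;  // ghost opposite v[i]
    dt.tets.push_back(T0);
    for (int f = 0; f < 4; ++f) {
      Tet G;
      G.v[0] = T0.v[(f + 1) & 3];
      G.v[1] = T0.v[(f + 2) & 3];
      G.v[2] = T0.v[(f + 3) & 3];
      G.v[3] = dt.INF;
      G.alive = true; G.bad = false;
      G.n[3] = 0;                      // across the hull face: the real tet
      G.n[0] = G.n[1] = G.n[2] = -1;   // filled below
      dt.tets.push_back(G);
    }
    // stitch ghost-to-ghost neighbours: ghosts f and g share the edge made
    // of the vertices common to both hull faces
    for (int a = 1; a <= 4; ++a)
      for (int b = a + 1; b <= 4; ++b) {
        // shared infinite face = (common edge, INF); find slots
        int* va = dt.tets[a].v;
        int* vb = dt.tets[b].v;
        for (int i = 0; i < 3; ++i) {
          bool in_b = va[i] == vb[0] || va[i] == vb[1] || va[i] == vb[2];
          if (!in_b) dt.tets[a].n[i] = b;
        }
        for (int i = 0; i < 3; ++i) {
          bool in_a = vb[i] == va[0] || vb[i] == va[1] || vb[i] == va[2];
          if (!in_a) dt.tets[b].n[i] = a;
        }
      }

    int fail_at = -1;
    for (int i = 0; i < n && !dt.failed; ++i) {
      int ip = order[i];
      if (ip == s0 || ip == s1 || ip == s2 || ip == s3) continue;
      dt.insert(ip);
      if (dt.failed) fail_at = i;
    }
    if (dt.failed) {
      if (std::getenv("CAVEX_DT_DEBUG"))
        Rcpp::Rcout << "attempt " << attempt << " failed at insert " << fail_at
                    << " ntets " << dt.tets.size() << "\n";
      continue;
    }

    std::vector<std::array<int, 4>> keep;
    double vol_tets = 0;
    for (auto& T : dt.tets) {
      if (!T.alive || dt.is_ghost(T)) continue;
      keep.push_back({T.v[0], T.v[1], T.v[2], T.v[3]});
      vol_tets += std::fabs(orient3d(dt.pts[T.v[0]], dt.pts[T.v[1]],
                                     dt.pts[T.v[2]], dt.pts[T.v[3]])) / 6.0;
    }
    if (keep.empty()) continue;

    // validation: the ghost faces must form a closed convex surface (the
    // hull of the working coordinates) and the finite tetrahedra must fill
    // exactly its enclosed volume; violations mark a corrupted run
    {
      bool ok = true;
      std::vector<std::array<int, 3>> gf;
      std::unordered_map<uint64_t, int> ecount;
      for (auto& T : dt.tets) {
        if (!T.alive || !dt.is_ghost(T)) continue;
        int fc[3];
        dt.ghost_face(T, fc);
        gf.push_back({fc[0], fc[1], fc[2]});
        for (int e = 0; e < 3 && ok; ++e) {
          int a = fc[e], b = fc[(e + 1) % 3];
          uint64_t key = a < b ? (uint64_t)(uint32_t)a << 32 | (uint32_t)b
                               : (uint64_t)(uint32_t)b << 32 | (uint32_t)a;
          if (++ecount[key] > 2) ok = false;
        }
      }
      for (auto& kv : ecount) if (kv.second != 2) { ok = false; break; }
      double vhull = 0;
      // unit-box scale; jittered attempts may protrude by ~jmag per point
      const double conv_tol = std::max(1e-9, 20.0 * jmag);
      for (size_t i = 0; i < gf.size() && ok; ++i) {
        V3 A = dt.pts[gf[i][0]], B = dt.pts[gf[i][1]], C = dt.pts[gf[i][2]];
        double oi = orient3d(A, B, C, dt.interior);
        if (oi == 0) { ok = false; break; }
        if (oi > 0) std::swap(B, C);  // outward: interior on negative side
        vhull += orient3d(dt.interior, A, B, C) / 6.0;
        // convexity: no point may lie beyond this hull face
        V3 nrm = cross(B - A, C - A);
        double nl = norm(nrm);
        if (nl == 0) { ok = false; break; }
        double off = dot(nrm, A);
        for (int k = 0; k < n; ++k)
          if (dot(nrm, dt.pts[k]) - off > conv_tol * nl) { ok = false; break; }
      }
      if (!ok || std::fabs(vol_tets - vhull) > 1e-9 * std::max(vhull, 1e-12)) {
        if (std::getenv("CAVEX_DT_DEBUG"))
          Rcpp::Rcout << "attempt " << attempt << " validation: ok=" << ok
                      << " tets " << vol_tets << " hull " << vhull << "\n";
        continue;
      }
    }
    IntegerMatrix out((int)keep.size(), 4);
    for (size_t i = 0; i < keep.size(); ++i) {
      std::array<int, 4> t = keep[i];
      if (orient3d(orig[t[0]], orig[t[1]], orig[t[2]], orig[t[3]]) < 0)
        std::swap(t[2], t[3]);
      for (int j = 0; j < 4; ++j) out(i, j) = t[j];
    }
    return out;
  }
  stop("Delaunay tetrahedralisation failed: degenerate point cloud");
}

// circumradius of each tetrahedron; slivers (near-singular) get +Inf
// [[Rcpp::export(name = ".C_circumradii")]]
NumericVector C_circumradii(NumericMatrix points, IntegerMatrix tets) {
  std::vector<V3> p = mat_to_pts(points);
  int m = tets.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const V3& a = p[tets(i, 0)];
    V3 b = p[tets(i, 1)] - a, c = p[tets(i, 2)] - a, d = p[tets(i, 3)] - a;
    double A[9] = {2 * b.x, 2 * b.y, 2 * b.z,
                   2 * c.x, 2 * c.y, 2 * c.z,
                   2 * d.x, 2 * d.y, 2 * d.z};
    double rhs[3] = {dot(b, b), dot(c, c), dot(d, d)};
    double det = A[0] * (A[4] * A[8] - A[5] * A[7])
               - A[1] * (A[3] * A[8] - A[5] * A[6])
               + A[2] * (A[3] * A[7] - A[4] * A[6]);
    double scale = std::cbrt(std::fabs(rhs[0] * rhs[1] * rhs[2]));
    if (!(std::fabs(det) > 1e-10 * scale * std::sqrt(scale)) || scale == 0) {
      out[i] = R_PosInf;  // sliver: dropped for any finite alpha
      continue;
    }
    double x = (rhs[0] * (A[4] * A[8] - A[5] * A[7])
              - A[1] * (rhs[1] * A[8] - A[5] * rhs[2])
              + A[2] * (rhs[1] * A[7] - A[4] * rhs[2])) / det;
    double y = (A[0] * (rhs[1] * A[8] - A[5] * rhs[2])
              - rhs[0] * (A[3] * A[8] - A[5] * A[6])
              + A[2] * (A[3] * rhs[2] - rhs[1] * A[6])) / det;
    double z = (A[0] * (A[4] * rhs[2] - rhs[1] * A[7])
              - A[1] * (A[3] * rhs[2] - rhs[1] * A[6])
              + rhs[0] * (A[3] * A[7] - A[4] * A[6])) / det;
    out[i] = std::sqrt(x * x + y * y + z * z);
  }
  return out;
}

// batch point-in-complex test (barycentric tolerance ~ -1e-12 relative)
// [[Rcpp::export(name = ".C_points_in_tets")]]
LogicalVector C_points_in_tets(NumericMatrix points, IntegerMatrix tets,
                               NumericMatrix query) {
  std::vector<V3> p = mat_to_pts(points), q = mat_to_pts(query);
  int m = tets.nrow(), nq = query.nrow();
  LogicalVector out(nq, false);
  std::vector<std::array<double, 6>> bb(m);
  for (int i = 0; i < m; ++i) {
    std::array<double, 6> b = {R_PosInf, R_PosInf, R_PosInf,
                               R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 4; ++j) {
      const V3& v = p[tets(i, j)];
      b[0] = std::min(b[0], v.x); b[1] = std::min(b[1], v.y); b[2] = std::min(b[2], v.z);
      b[3] = std::max(b[3], v.x); b[4] = std::max(b[4], v.y); b[5] = std::max(b[5], v.z);
    }
    bb[i] = b;
  }
  for (int k = 0; k < nq; ++k) {
    const V3& x = q[k];
    for (int i = 0; i < m && !out[k]; ++i) {
      if (x.x < bb[i][0] - 1e-9 || x.x > bb[i][3] + 1e-9 ||
          x.y < bb[i][1] - 1e-9 || x.y > bb[i][4] + 1e-9 ||
          x.z < bb[i][2] - 1e-9 || x.z > bb[i][5] + 1e-9) continue;
      const V3& a = p[tets(i, 0)];
      const V3& b = p[tets(i, 1)];
      const V3& c = p[tets(i, 2)];
      const V3& d = p[tets(i, 3)];
      double V = orient3d(a, b, c, d);
      if (V == 0) continue;
      double sgn = V > 0 ? 1.0 : -1.0;
      double tol = -1e-12 * std::fabs(V);
      double s1 = orient3d(x, b, c, d) * sgn;
      double s2 = orient3d(a, x, c, d) * sgn;
      double s3 = orient3d(a, b, x, d) * sgn;
      double s4 = orient3d(a, b, c, x) * sgn;
      if (s1 >= tol && s2 >= tol && s3 >= tol && s4 >= tol) out[k] = true;
    }
  }
  return out;
}
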