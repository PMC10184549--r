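// Line-of-sight machinery: AABB BVH over triangles, any-hit segment queries
// (with the triangles incident to the target vertex excluded), a brute-force
// all-pairs variant kept as the semantic oracle, and all-hits ray casting
// used to seed interior points of enclosed cavities.

#include "geom.h"
#include <algorithm>

using namespace Rcpp;

namespace {

struct AABB {
  V3 lo, hi;
  AABB() : lo(R_PosInf, R_PosInf, R_PosInf), hi(R_NegInf, R_NegInf, R_NegInf) {}
  void grow(const V3& p) {
    lo = V3(std::min(lo.x, p.x), std::min(lo.y, p.y), std::min(lo.z, p.z));
    hi = V3(std::max(hi.x, p.x), std::max(hi.y, p.y), std::max(hi.z, p.z));
  }
  void grow(const AABB& b) { grow(b.lo); grow(b.hi); }
  // slab test for segment o + t*d, t in [0, tmax]
  bool hit(const V3& o, const V3& inv_d, double tmax) const {
    double t0 = 0, t1 = tmax;
    for (int a = 0; a < 3; ++a) {
      double ta = (lo[a] - o[a]) * inv_d[a];
      double tb = (hi[a] - o[a]) * inv_d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1 + 1e-12) return false;
    }
    return true;
  }
};

struct BVH {
  struct Node { AABB box; int left, right, start, count; };
  std::vector<Node> nodes;
  std::vector<int> order;                 // face indices
  const std::vector<V3>* verts;
  const IntegerMatrix* faces;

  void build(const std::vector<V3>& v, const IntegerMatrix& f) {
    verts = &v; faces = &f;
    int nf = f.nrow();
    order.resize(nf);
    std::vector<V3> cent(nf);
    for (int i = 0; i < nf; ++i) {
      order[i] = i;
      cent[i] = (v[f(i, 0)] + v[f(i, 1)] + v[f(i, 2)]) * (1.0 / 3.0);
    }
    nodes.reserve(2 * nf);
    rec(0, nf, cent);
  }

  int rec(int start, int count, const std::vector<V3>& cent) {
    Node nd;
    nd.start = start; nd.count = count; nd.left = nd.right = -1;
    for (int i = start; i < start + count; ++i)
      for (int j = 0; j < 3; ++j) nd.box.grow((*verts)[(*faces)(order[i], j)]);
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count > 4) {
      V3 ext = nd.box.hi - nd.box.lo;
      int ax = ext.x > ext.y ? (ext.x > ext.z ? 0 : 2) : (ext.y > ext.z ? 1 : 2);
      int mid = start + count / 2;
      std::nth_element(order.begin() + start, order.begin() + mid,
                       order.begin() + start + count,
                       [&](int a, int b) { return cent[a][ax] < cent[b][ax]; });
      int l = rec(start, mid - start, cent);
      int r = rec(mid, start + count - mid, cent);
      nodes[id].left = l;
      nodes[id].right = r;
      nodes[id].count = 0;
    }
    return id;
  }

  // any intersection of segment [o, o + d] (t in [0,1]) with a triangle not
  // incident to vertex `skip`
  bool any_hit(const V3& o, const V3& d, int skip) const {
    V3 inv(1.0 / (d.x == 0 ? 1e-300 : d.x),
           1.0 / (d.y == 0 ? 1e-300 : d.y),
           1.0 / (d.z == 0 ? 1e-300 : d.z));
    std::vector<int> stack_{0};
    stack_.reserve(64);
    while (!stack_.empty()) {
      int id = stack_.back(); stack_.pop_back();
      const Node& nd = nodes[id];
      if (!nd.box.hit(o, inv, 1.0)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int fi = order[i];
          int a = (*faces)(fi, 0), b = (*faces)(fi, 1), c = (*faces)(fi, 2);
          if (a == skip || b == skip || c == skip) continue;
          if (seg_tri_hit(o, d, 0.0, 1.0, (*verts)[a], (*verts)[b], (*verts)[c]))
            return true;
        }
      } else {
        stack_.push_back(nd.left);
        stack_.push_back(nd.right);
      }
    }
    return false;
  }

  // all hits along ray o + t*d, t in [0, tmax]
  void all_hits(const V3& o, const V3& d, double tmax, std::vector<double>& ts) const {
    V3 inv(1.0 / (d.x == 0 ? 1e-300 : d.x),
           1.0 / (d.y == 0 ? 1e-300 : d.y),
           1.0 / (d.z == 0 ? 1e-300 : d.z));
    std::vector<int> stack_{0};
    while (!stack_.empty()) {
      int id = stack_.back(); stack_.pop_back();
      const Node& nd = nodes[id];
      if (!nd.box.hit(o, inv, tmax)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int fi = order[i];
          double t;
          if (seg_tri_hit(o, d, 0.0, tmax, (*verts)[(*faces)(fi, 0)],
                          (*verts)[(*faces)(fi, 1)], (*verts)[(*faces)(fi, 2)], &t))
            ts.push_back(t);
        }
      } else {
        stack_.push_back(nd.left);
        stack_.push_back(nd.right);
      }
    }
  }
};

// open segment from pov towards vertex v, shortened by eps at both ends
inline bool segment_for(const V3& pov, const V3& v, double eps, V3& o, V3& d) {
  V3 dir = v - pov;
  double len = norm(dir);
  if (len <= 2 * eps) return false;  // degenerate: treat as visible
  V3 u = dir * (1.0 / len);
  o = pov + u * eps;
  d = u * (len - 2 * eps);
  return true;
}

}  // namespace

// visibility of every vertex from one or more POVs.
// any_pov = true  -> logical vector, visible from >= 1 POV (early exit)
// any_pov = false -> logical matrix nverts x npov
// [[Rcpp::export(name = ".C_visibility")]]
SEXP C_visibility(NumericMatrix verts, IntegerMatrix faces, NumericMatrix povs,
                  double eps, bool any_pov) {
  std::vector<V3> v = mat_to_pts(verts);
  std::vector<V3> pv = mat_to_pts(povs);
  BVH bvh;
  bvh.build(v, faces);
  int nv = (int)v.size(), np = (int)pv.size();
  if (any_pov) {
    LogicalVector out(nv, false);
    for (int i = 0; i < nv; ++i) {
      for (int p = 0; p < np; ++p) {
        V3 o, d;
        if (!segment_for(pv[p], v[i], eps, o, d)) { out[i] = true; break; }
        if (!bvh.any_hit(o, d, i)) { out[i] = true; break; }
      }
    }
    return out;
  }
  LogicalMatrix out(nv, np);
  for (int p = 0; p < np; ++p)
    for (int i = 0; i < nv; ++i) {
      V3 o, d;
      if (!segment_for(pv[p], v[i], eps, o, d)) { out(i, p) = true; continue; }
      out(i, p) = !bvh.any_hit(o, d, i);
    }
  return out;
}

// brute-force all-pairs oracle (no BVH; identical per-triangle predicate)
// [[Rcpp::export(name = ".C_visibility_brute")]]
LogicalVector C_visibility_brute(NumericMatrix verts, IntegerMatrix faces,
                                 NumericMatrix povs, double eps) {
  std::vector<V3> v = mat_to_pts(verts);
  std::vector<V3> pv = mat_to_pts(povs);
  int nv = (int)v.size(), np = (int)pv.size(), nf = faces.nrow();
  LogicalVector out(nv, false);
  for (int i = 0; i < nv; ++i) {
    for (int p = 0; p < np && !out[i]; ++p) {
      V3 o, d;
      if (!segment_for(pv[p], v[i], eps, o, d)) { out[i] = true; break; }
      bool blocked = false;
      for (int f = 0; f < nf && !blocked; ++f) {
        int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
        if (a == i || b == i || c == i) continue;
        blocked = seg_tri_hit(o, d, 0.0, 1.0, v[a], v[b], v[c]);
      }
      if (!blocked) out[i] = true;
    }
  }
  return out;
}

// all intersection parameters t (ascending) for each ray origin/direction
// [[Rcpp::export(name = ".C_ray_hits")]]
List C_ray_hits(NumericMatrix verts, IntegerMatrix faces,
                NumericMatrix origins, NumericMatrix dirs, double tmax) {
  std::vector<V3> v = mat_to_pts(verts);
  BVH bvh;
  bvh.build(v, faces);
  int nr = origins.nrow();
  List out(nr);
  for (int r = 0; r < nr; ++r) {
    V3 o(origins(r, 0), origins(r, 1), origins(r, 2));
    V3 d(dirs(r, 0), dirs(r, 1), dirs(r, 2));
    std::vector<double> ts;
    bvh.all_hits(o, d, tmax, ts);
    std::sort(ts.begin(), ts.end());
    out[r] = NumericVector(ts.begin(), ts.end());
  }
  return out;
}

// first intersection along each ray: parameter t and 0-based face index
// (t = -1 when nothing is hit)
// [[Rcpp::export(name = ".C_first_hit")]]
List C_first_hit(NumericMatrix verts, IntegerMatrix faces,
                 NumericMatrix origins, NumericMatrix dirs, double tmax) {
  std::vector<V3> v = mat_to_pts(verts);
  BVH bvh;
  bvh.build(v, faces);
  int nr = origins.nrow();
  NumericVector t_out(nr, -1.0);
  IntegerVector f_out(nr, -1);
  for (int r = 0; r < nr; ++r) {
    V3 o(origins(r, 0), origins(r, 1), origins(r, 2));
    V3 d(dirs(r, 0), dirs(r, 1), dirs(r, 2));
    std::vector<double> ts;
    // collect all hits, then pick the closest with its face
    V3 inv(1.0 / (d.x == 0 ? 1e-300 : d.x),
           1.0 / (d.y == 0 ? 1e-300 : d.y),
           1.0 / (d.z == 0 ? 1e-300 : d.z));
    double best_t = R_PosInf;
    int best_f = -1;
    std::vector<int> stack_{0};
    while (!stack_.empty()) {
      int id = stack_.back(); stack_.pop_back();
      const BVH::Node& nd = bvh.nodes[id];
      if (!nd.box.hit(o, inv, tmax)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int fi = bvh.order[i];
          double t;
          if (seg_tri_hit(o, d, 0.0, tmax, v[faces(fi, 0)], v[faces(fi, 1)],
                          v[faces(fi, 2)], &t) && t < best_t) {
            best_t = t;
            best_f = fi;
          }
        }
      } else {
        stack_.push_back(nd.left);
        stack_.push_back(nd.right);
      }
    }
    if (best_f >= 0) { t_out[r] = best_t; f_out[r] = best_f; }
  }
  return List::create(_["t"] = t_out, _["face"] = f_out);
}

// squared distance from each query point to the nearest mesh vertex
// [[Rcpp::export(name = ".C_min_dist2")]]
NumericVector C_min_dist2(NumericMatrix verts, NumericMatrix query) {
  std::vector<V3> v = mat_to_pts(verts), q = mat_to_pts(query);
  NumericVector out(q.size());
  for (size_t i = 0; i < q.size(); ++i) {
    double best = R_PosInf;
    for (size_t j = 0; j < v.size(); ++j) {
      V3 d = q[i] - v[j];
      double d2 = dot(d, d);
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}
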