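// Mesh-level operations: half-space cutting with exact triangle splitting,
// shared-vertex connected components, closedness / orientation checks,
// divergence-theorem volume, and voxelisation of an alpha complex.

#include "geom.h"
#include <unordered_map>
#include <algorithm>
#include <functional>

using namespace Rcpp;

// Cut by plane, keeping the requested half-space. Triangles straddling the
// plane are split; intersection vertices are welded via an edge cache so the
// cut stays conformal. Vertices within `tol` of the plane count as on it and
// are kept on both sides.
// [[Rcpp::export(name = ".C_cut_mesh")]]
List C_cut_mesh(NumericMatrix verts, IntegerMatrix faces, NumericVector origin,
                NumericVector normal, int keep_sign, double tol) {
  std::vector<V3> v = mat_to_pts(verts);
  V3 o(origin[0], origin[1], origin[2]), nrm(normal[0], normal[1], normal[2]);
  int nv = (int)v.size(), nf = faces.nrow();

  std::vector<double> d(nv);
  std::vector<int> side(nv);
  for (int i = 0; i < nv; ++i) {
    d[i] = dot(v[i] - o, nrm);
    side[i] = d[i] > tol ? 1 : (d[i] < -tol ? -1 : 0);
  }

  std::vector<V3> new_verts = v;
  std::vector<std::array<int, 3>> out_faces;
  std::unordered_map<uint64_t, int> edge_cache;

  auto edge_point = [&](int a, int b) -> int {
    uint64_t key = a < b ? (uint64_t)a << 32 | (uint32_t)b
                         : (uint64_t)b << 32 | (uint32_t)a;
    auto it = edge_cache.find(key);
    if (it != edge_cache.end()) return it->second;
    double t = d[a] / (d[a] - d[b]);
    V3 p = v[a] + (v[b] - v[a]) * t;
    new_verts.push_back(p);
    int id = (int)new_verts.size() - 1;
    edge_cache[key] = id;
    return id;
  };

  for (int f = 0; f < nf; ++f) {
    int tri[3] = {faces(f, 0), faces(f, 1), faces(f, 2)};
    int spos = 0, sneg = 0;
    for (int k = 0; k < 3; ++k) {
      if (side[tri[k]] * keep_sign > 0) spos++;
      else if (side[tri[k]] * keep_sign < 0) sneg++;
    }
    if (sneg == 0) {                       // fully kept (on-plane counts in)
      out_faces.push_back({tri[0], tri[1], tri[2]});
      continue;
    }
    if (spos == 0) continue;               // fully discarded
    // Sutherland-Hodgman clip of the triangle against the kept half-space
    int poly[4]; int np = 0;
    for (int k = 0; k < 3; ++k) {
      int a = tri[k], b = tri[(k + 1) % 3];
      int sa = side[a] * keep_sign, sb = side[b] * keep_sign;
      if (sa >= 0) poly[np++] = a;
      if ((sa > 0 && sb < 0) || (sa < 0 && sb > 0)) poly[np++] = edge_point(a, b);
    }
    if (np == 3) {
      out_faces.push_back({poly[0], poly[1], poly[2]});
    } else if (np == 4) {
      out_faces.push_back({poly[0], poly[1], poly[2]});
      out_faces.push_back({poly[0], poly[2], poly[3]});
    }
  }

  // compact vertex set
  std::vector<int> remap(new_verts.size(), -1);
  int nkeep = 0;
  for (auto& tr : out_faces)
    for (int k = 0; k < 3; ++k)
      if (remap[tr[k]] < 0) remap[tr[k]] = nkeep++;
  NumericMatrix vm(nkeep, 3);
  for (size_t i = 0; i < new_verts.size(); ++i)
    if (remap[i] >= 0) {
      vm(remap[i], 0) = new_verts[i].x;
      vm(remap[i], 1) = new_verts[i].y;
      vm(remap[i], 2) = new_verts[i].z;
    }
  IntegerMatrix fm((int)out_faces.size(), 3);
  for (size_t i = 0; i < out_faces.size(); ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = remap[out_faces[i][k]];
  return List::create(_["vertices"] = vm, _["faces"] = fm);
}

// face component labels via union-find on shared vertices (0-based labels,
// arbitrary order; relabelled in R)
// [[Rcpp::export(name = ".C_face_components")]]
IntegerVector C_face_components(IntegerMatrix faces, int nverts) {
  std::vector<int> parent(nverts);
  for (int i = 0; i < nverts; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = find(faces(f, 0)), b = find(faces(f, 1)), c = find(faces(f, 2));
    parent[b] = a;
    parent[c] = find(a);
  }
  IntegerVector out(nf);
  for (int f = 0; f < nf; ++f) out[f] = find(faces(f, 0));
  return out;
}

// closed + consistently oriented check: every directed edge must appear
// exactly once, and its reverse exactly once
// [[Rcpp::export(name = ".C_edge_status")]]
List C_edge_status(IntegerMatrix faces) {
  std::unordered_map<uint64_t, int> dir_count;
  int nf = faces.nrow();
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      uint64_t a = faces(f, k), b = faces(f, (k + 1) % 3);
      dir_count[a << 32 | b]++;
    }
  int n_bad_dup = 0, n_boundary = 0;
  for (auto& kv : dir_count) {
    if (kv.second > 1) n_bad_dup++;
    uint64_t rev = (kv.first & 0xffffffffULL) << 32 | (kv.first >> 32);
    if (dir_count.find(rev) == dir_count.end()) n_boundary++;
  }
  return List::create(_["closed_oriented"] = (n_bad_dup == 0 && n_boundary == 0),
                      _["n_boundary_edges"] = n_boundary,
                      _["n_nonmanifold_edges"] = n_bad_dup);
}

// [[Rcpp::export(name = ".C_signed_volume")]]
double C_signed_volume(NumericMatrix verts, IntegerMatrix faces) {
  std::vector<V3> v = mat_to_pts(verts);
  double vol = 0;
  for (int f = 0; f < faces.nrow(); ++f) {
    const V3& a = v[faces(f, 0)];
    const V3& b = v[faces(f, 1)];
    const V3& c = v[faces(f, 2)];
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return vol;
}

// Voxelise an alpha complex: centre-in-complex flags (by rasterising each
// tetrahedron's bounding box) and has-vertex flags (half-open [low, high)
// voxel assignment of the COI vertex cloud).
// [[Rcpp::export(name = ".C_voxelize")]]
List C_voxelize(NumericMatrix points, IntegerMatrix tets, NumericMatrix coi,
                NumericVector origin, double spacing, IntegerVector dims) {
  std::vector<V3> p = mat_to_pts(points);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  V3 o(origin[0], origin[1], origin[2]);
  size_t ncell = (size_t)nx * ny * nz;
  LogicalVector inside(ncell, false), hasvert(ncell, false);

  for (int t = 0; t < tets.nrow(); ++t) {
    const V3& a = p[tets(t, 0)];
    const V3& b = p[tets(t, 1)];
    const V3& c = p[tets(t, 2)];
    const V3& d = p[tets(t, 3)];
    double V = orient3d(a, b, c, d);
    if (V == 0) continue;
    double sgn = V > 0 ? 1.0 : -1.0;
    double tol = -1e-12 * std::fabs(V);
    V3 lo(std::min({a.x, b.x, c.x, d.x}), std::min({a.y, b.y, c.y, d.y}),
          std::min({a.z, b.z, c.z, d.z}));
    V3 hi(std::max({a.x, b.x, c.x, d.x}), std::max({a.y, b.y, c.y, d.y}),
          std::max({a.z, b.z, c.z, d.z}));
    int i0 = std::max(0, (int)std::floor((lo.x - o.x) / spacing - 0.5));
    int j0 = std::max(0, (int)std::floor((lo.y - o.y) / spacing - 0.5));
    int k0 = std::max(0, (int)std::floor((lo.z - o.z) / spacing - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((hi.x - o.x) / spacing - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((hi.y - o.y) / spacing - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((hi.z - o.z) / spacing - 0.5));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          size_t id = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
          if (inside[id]) continue;
          V3 x(o.x + (i + 0.5) * spacing, o.y + (j + 0.5) * spacing,
               o.z + (k + 0.5) * spacing);
          double s1 = orient3d(x, b, c, d) * sgn;
          double s2 = orient3d(a, x, c, d) * sgn;
          double s3 = orient3d(a, b, x, d) * sgn;
          double s4 = orient3d(a, b, c, x) * sgn;
          if (s1 >= tol && s2 >= tol && s3 >= tol && s4 >= tol) inside[id] = true;
        }
  }
  for (int i = 0; i < coi.nrow(); ++i) {
    int ix = (int)std::floor((coi(i, 0) - o.x) / spacing);
    int iy = (int)std::floor((coi(i, 1) - o.y) / spacing);
    int iz = (int)std::floor((coi(i, 2) - o.z) / spacing);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) continue;
    hasvert[(size_t)ix + (size_t)nx * (iy + (size_t)ny * iz)] = true;
  }
  return List::create(_["inside"] = inside, _["hasvert"] = hasvert);
}

// total |tetra| volume of a complex (mm^3)
// [[Rcpp::export(name = ".C_tet_volumes")]]
NumericVector C_tet_volumes(NumericMatrix points, IntegerMatrix tets) {
  std::vector<V3> p = mat_to_pts(points);
  NumericVector out(tets.nrow());
  for (int t = 0; t < tets.nrow(); ++t)
    out[t] = std::fabs(orient3d(p[tets(t, 0)], p[tets(t, 1)], p[tets(t, 2)],
                                p[tets(t, 3)])) / 6.0;
  return out;
}
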