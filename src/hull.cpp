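// Quickhull 3D convex hull; used as the independent volume oracle for the
// alpha -> Inf limit of the alpha-shape complex.

#include "geom.h"
#include <algorithm>

using namespace Rcpp;

namespace {

struct HFace {
  int v[3];
  int n[3];            // neighbour across edge (v[i], v[(i+1)%3])
  V3 normal;           // non-unit outward normal
  double off;          // dot(normal, v0)
  std::vector<int> outside;
  bool alive = true;
};

double fdist(const HFace& f, const V3& p) { return dot(f.normal, p) - f.off; }

}  // namespace

// [[Rcpp::export(name = ".C_convex_hull")]]
List C_convex_hull(NumericMatrix points) {
  std::vector<V3> p = mat_to_pts(points);
  int n = (int)p.size();
  if (n < 4) stop("need at least 4 points for a 3D hull");

  double scale = 0;
  V3 lo = p[0], hi = p[0];
  for (auto& q : p) {
    lo = V3(std::min(lo.x, q.x), std::min(lo.y, q.y), std::min(lo.z, q.z));
    hi = V3(std::max(hi.x, q.x), std::max(hi.y, q.y), std::max(hi.z, q.z));
  }
  scale = std::max({hi.x - lo.x, hi.y - lo.y, hi.z - lo.z});
  if (scale <= 0) stop("degenerate point cloud");
  double eps = 1e-12 * scale;

  // initial simplex: extremes on x, then farthest from segment, then plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (p[i].x < p[i0].x) i0 = i;
    if (p[i].x > p[i1].x) i1 = i;
  }
  if (i0 == i1) i1 = (i0 + 1) % n;
  int i2 = -1; double best = eps;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(p[i] - p[i0], p[i1] - p[i0]));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate (collinear) point cloud");
  int i3 = -1; best = eps * scale;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(orient3d(p[i0], p[i1], p[i2], p[i]));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate (coplanar) point cloud");
  if (orient3d(p[i0], p[i1], p[i2], p[i3]) > 0) std::swap(i1, i2);

  std::vector<HFace> faces;
  auto mkface = [&](int a, int b, int c) {
    HFace f;
    f.v[0] = a; f.v[1] = b; f.v[2] = c;
    f.normal = cross(p[b] - p[a], p[c] - p[a]);
    f.off = dot(f.normal, p[a]);
    f.n[0] = f.n[1] = f.n[2] = -1;
    return f;
  };
  faces.push_back(mkface(i0, i1, i2));
  faces.push_back(mkface(i0, i3, i1));
  faces.push_back(mkface(i1, i3, i2));
  faces.push_back(mkface(i2, i3, i0));
  auto link = [&](int fa, int fb) {
    for (int ea = 0; ea < 3; ++ea)
      for (int eb = 0; eb < 3; ++eb) {
        int a1 = faces[fa].v[ea], a2 = faces[fa].v[(ea + 1) % 3];
        int b1 = faces[fb].v[eb], b2 = faces[fb].v[(eb + 1) % 3];
        if (a1 == b2 && a2 == b1) { faces[fa].n[ea] = fb; faces[fb].n[eb] = fa; }
      }
  };
  for (int a = 0; a < 4; ++a) for (int b = a + 1; b < 4; ++b) link(a, b);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : faces)
      if (fdist(f, p[i]) > eps) { f.outside.push_back(i); break; }
  }

  std::vector<int> pending;
  for (int i = 0; i < (int)faces.size(); ++i)
    if (!faces[i].outside.empty()) pending.push_back(i);

  while (!pending.empty()) {
    int fi = pending.back(); pending.pop_back();
    if (!faces[fi].alive || faces[fi].outside.empty()) continue;
    // farthest point
    int far = -1; double fd = -1;
    for (int i : faces[fi].outside) {
      double d = fdist(faces[fi], p[i]);
      if (d > fd) { fd = d; far = i; }
    }
    const V3& q = p[far];
    // visible region BFS
    std::vector<int> visible, stack_{fi};
    std::vector<bool> seen(faces.size(), false);
    seen[fi] = true;
    while (!stack_.empty()) {
      int f = stack_.back(); stack_.pop_back();
      visible.push_back(f);
      for (int e = 0; e < 3; ++e) {
        int nb = faces[f].n[e];
        if (nb < 0 || seen[nb] || !faces[nb].alive) continue;
        if (fdist(faces[nb], q) > eps) { seen[nb] = true; stack_.push_back(nb); }
      }
    }
    // horizon edges (edge of visible face whose neighbour is not visible)
    struct HEdge { int a, b, outer, outer_edge; };
    std::vector<HEdge> horizon;
    for (int f : visible)
      for (int e = 0; e < 3; ++e) {
        int nb = faces[f].n[e];
        if (nb >= 0 && seen[nb]) continue;
        int oe = -1;
        for (int k = 0; k < 3; ++k) if (faces[nb].n[k] == f) oe = k;
        horizon.push_back({faces[f].v[e], faces[f].v[(e + 1) % 3], nb, oe});
      }
    // collect orphaned outside points
    std::vector<int> orphans;
    for (int f : visible) {
      for (int i : faces[f].outside) if (i != far) orphans.push_back(i);
      faces[f].alive = false;
      faces[f].outside.clear();
    }
    // new fan
    int base = (int)faces.size();
    for (size_t h = 0; h < horizon.size(); ++h) {
      HFace f = mkface(horizon[h].a, horizon[h].b, far);
      f.n[0] = horizon[h].outer;
      faces.push_back(f);
      faces[horizon[h].outer].n[horizon[h].outer_edge] = base + (int)h;
    }
    // stitch new faces to each other: edge (b, far) of face h meets
    // edge (far, a) of the face whose a == this b
    for (size_t h = 0; h < horizon.size(); ++h)
      for (size_t g = 0; g < horizon.size(); ++g) {
        if (faces[base + h].v[1] == faces[base + g].v[0]) {
          faces[base + h].n[1] = base + (int)g;
          faces[base + g].n[2] = base + (int)h;
        }
      }
    for (int i : orphans) {
      for (size_t h = 0; h < horizon.size(); ++h) {
        if (fdist(faces[base + h], p[i]) > eps) {
          faces[base + h].outside.push_back(i);
          break;
        }
      }
    }
    for (size_t h = 0; h < horizon.size(); ++h)
      if (!faces[base + h].outside.empty()) pending.push_back(base + (int)h);
  }

  // volume relative to interior point (mean of simplex) + face list
  V3 o = (p[i0] + p[i1] + p[i2] + p[i3]) * 0.25;
  double vol = 0;
  std::vector<std::array<int, 3>> out_faces;
  for (auto& f : faces) {
    if (!f.alive) continue;
    vol += orient3d(o, p[f.v[0]], p[f.v[2]], p[f.v[1]]) / 6.0;
    out_faces.push_back({f.v[0], f.v[1], f.v[2]});
  }
  vol = std::fabs(vol);
  IntegerMatrix fm((int)out_faces.size(), 3);
  for (size_t i = 0; i < out_faces.size(); ++i)
    for (int j = 0; j < 3; ++j) fm(i, j) = out_faces[i][j];
  return List::create(_["volume"] = vol, _["faces"] = fm);
}
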