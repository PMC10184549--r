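// Quadric error-metric (QEM) edge-collapse decimation. Boundary edges are
// constrained by perpendicular plane quadrics; collapses that flip or
// degenerate surviving triangles are rejected.

#include "geom.h"
#include <queue>
#include <set>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Quadric {
  // symmetric 4x4, upper triangle: a..j
  double q[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const V3& p) const {
    return q[0] * p.x * p.x + 2 * q[1] * p.x * p.y + 2 * q[2] * p.x * p.z +
           2 * q[3] * p.x + q[4] * p.y * p.y + 2 * q[5] * p.y * p.z +
           2 * q[6] * p.y + q[7] * p.z * p.z + 2 * q[8] * p.z + q[9];
  }
  bool optimal(V3& out) const {
    double A[9] = {q[0], q[1], q[2], q[1], q[4], q[5], q[2], q[5], q[7]};
    double b[3] = {-q[3], -q[6], -q[8]};
    double det = A[0] * (A[4] * A[8] - A[5] * A[7])
               - A[1] * (A[3] * A[8] - A[5] * A[6])
               + A[2] * (A[3] * A[7] - A[4] * A[6]);
    double tr = std::fabs(A[0]) + std::fabs(A[4]) + std::fabs(A[8]);
    if (std::fabs(det) < 1e-10 * tr * tr * tr + 1e-300) return false;
    out.x = (b[0] * (A[4] * A[8] - A[5] * A[7])
           - A[1] * (b[1] * A[8] - A[5] * b[2])
           + A[2] * (b[1] * A[7] - A[4] * b[2])) / det;
    out.y = (A[0] * (b[1] * A[8] - A[5] * b[2])
           - b[0] * (A[3] * A[8] - A[5] * A[6])
           + A[2] * (A[3] * b[2] - b[1] * A[6])) / det;
    out.z = (A[0] * (A[4] * b[2] - b[1] * A[7])
           - A[1] * (A[3] * b[2] - b[1] * A[6])
           + b[0] * (A[3] * A[7] - A[4] * A[6])) / det;
    return true;
  }
};

struct HeapItem {
  double cost;
  int a, b;         // a < b
  int va_ver, vb_ver;
  V3 pos;
  bool operator<(const HeapItem& o) const { return cost > o.cost; }  // min-heap
};

}  // namespace

// [[Rcpp::export(name = ".C_decimate")]]
List C_decimate(NumericMatrix verts, IntegerMatrix faces, int target_faces) {
  std::vector<V3> v = mat_to_pts(verts);
  int nv = (int)v.size(), nf = faces.nrow();
  std::vector<std::array<int, 3>> f(nf);
  for (int i = 0; i < nf; ++i) f[i] = {faces(i, 0), faces(i, 1), faces(i, 2)};
  std::vector<bool> f_alive(nf, true), v_alive(nv, true);
  std::vector<int> v_version(nv, 0);
  std::vector<std::vector<int>> vf(nv);  // incident faces
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) vf[f[i][k]].push_back(i);

  // face plane helper
  auto face_normal = [&](int fi, const std::vector<V3>& pos) {
    return cross(pos[f[fi][1]] - pos[f[fi][0]], pos[f[fi][2]] - pos[f[fi][0]]);
  };

  // vertex quadrics from incident face planes (area-weighted)
  std::vector<Quadric> Q(nv);
  for (int i = 0; i < nf; ++i) {
    V3 n = face_normal(i, v);
    double area2 = norm(n);
    if (area2 <= 0) continue;
    V3 un = n * (1.0 / area2);
    double d = -dot(un, v[f[i][0]]);
    for (int k = 0; k < 3; ++k) Q[f[i][k]].add_plane(un.x, un.y, un.z, d, area2 * 0.5);
  }

  // boundary edges: add perpendicular constraint planes
  std::unordered_map<uint64_t, int> edge_faces;
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int a = f[i][k], b = f[i][(k + 1) % 3];
      uint64_t key = a < b ? (uint64_t)a << 32 | (uint32_t)b
                           : (uint64_t)b << 32 | (uint32_t)a;
      edge_faces[key]++;
    }
  double bbox_diag = 0;
  {
    V3 lo = v[0], hi = v[0];
    for (auto& p : v) {
      lo = V3(std::min(lo.x, p.x), std::min(lo.y, p.y), std::min(lo.z, p.z));
      hi = V3(std::max(hi.x, p.x), std::max(hi.y, p.y), std::max(hi.z, p.z));
    }
    bbox_diag = norm(hi - lo);
  }
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int a = f[i][k], b = f[i][(k + 1) % 3];
      uint64_t key = a < b ? (uint64_t)a << 32 | (uint32_t)b
                           : (uint64_t)b << 32 | (uint32_t)a;
      if (edge_faces[key] != 1) continue;
      V3 fn = face_normal(i, v);
      double fl = norm(fn);
      if (fl <= 0) continue;
      V3 e = v[b] - v[a];
      V3 cn = cross(e, fn * (1.0 / fl));
      double cl = norm(cn);
      if (cl <= 0) continue;
      cn = cn * (1.0 / cl);
      double d = -dot(cn, v[a]);
      Quadric bq;
      bq.add_plane(cn.x, cn.y, cn.z, d, bbox_diag * bbox_diag);
      Q[a].add(bq);
      Q[b].add(bq);
    }

  std::priority_queue<HeapItem> heap;
  auto push_edge = [&](int a, int b) {
    if (a == b) return;
    if (a > b) std::swap(a, b);
    Quadric q = Q[a];
    q.add(Q[b]);
    V3 pos;
    if (!q.optimal(pos)) {
      V3 mid = (v[a] + v[b]) * 0.5;
      double cm = q.eval(mid), ca = q.eval(v[a]), cb = q.eval(v[b]);
      pos = mid;
      if (ca < cm) { pos = v[a]; cm = ca; }
      if (cb < cm) { pos = v[b]; }
    }
    heap.push({q.eval(pos), a, b, v_version[a], v_version[b], pos});
  };
  for (auto& kv : edge_faces) {
    int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xffffffffULL);
    push_edge(a, b);
  }

  int alive_faces = nf;
  std::vector<int> scratch;
  while (alive_faces > target_faces && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int a = it.a, b = it.b;
    if (!v_alive[a] || !v_alive[b]) continue;
    if (v_version[a] != it.va_ver || v_version[b] != it.vb_ver) continue;
    // still an edge?
    bool adjacent = false;
    for (int fi : vf[a]) {
      if (!f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (f[fi][k] == b) { adjacent = true; break; }
      if (adjacent) break;
    }
    if (!adjacent) continue;

    // validity: no surviving face may flip or collapse
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int vx = pass == 0 ? a : b;
      for (int fi : vf[vx]) {
        if (!f_alive[fi]) continue;
        bool has_both = false;
        for (int k = 0; k < 3; ++k)
          if (f[fi][k] == (pass == 0 ? b : a)) has_both = true;
        if (has_both) continue;  // face dies with the collapse
        V3 p[3];
        for (int k = 0; k < 3; ++k) {
          int vi = f[fi][k];
          p[k] = (vi == a || vi == b) ? it.pos : v[vi];
        }
        V3 n_new = cross(p[1] - p[0], p[2] - p[0]);
        V3 n_old = face_normal(fi, v);
        if (norm(n_new) < 1e-14 * bbox_diag * bbox_diag || dot(n_new, n_old) <= 0) {
          ok = false;
          break;
        }
      }
    }
    if (!ok) continue;

    // collapse b into a at it.pos
    v[a] = it.pos;
    Q[a].add(Q[b]);
    v_alive[b] = false;
    scratch.clear();
    for (int fi : vf[b]) {
      if (!f_alive[fi]) continue;
      bool has_a = false;
      for (int k = 0; k < 3; ++k) if (f[fi][k] == a) has_a = true;
      if (has_a) {
        f_alive[fi] = false;
        alive_faces--;
      } else {
        for (int k = 0; k < 3; ++k) if (f[fi][k] == b) f[fi][k] = a;
        vf[a].push_back(fi);
      }
    }
    v_version[a]++;
    v_version[b]++;
    // re-queue edges around a
    std::set<int> nbrs;
    for (int fi : vf[a]) {
      if (!f_alive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (f[fi][k] != a) nbrs.insert(f[fi][k]);
    }
    for (int w : nbrs) push_edge(a, w);
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nkeep = 0;
  std::vector<std::array<int, 3>> fout;
  for (int i = 0; i < nf; ++i) {
    if (!f_alive[i]) continue;
    for (int k = 0; k < 3; ++k)
      if (remap[f[i][k]] < 0) remap[f[i][k]] = nkeep++;
    fout.push_back(f[i]);
  }
  NumericMatrix vm(nkeep, 3);
  for (int i = 0; i < nv; ++i)
    if (remap[i] >= 0) {
      vm(remap[i], 0) = v[i].x;
      vm(remap[i], 1) = v[i].y;
      vm(remap[i], 2) = v[i].z;
    }
  IntegerMatrix fm((int)fout.size(), 3);
  for (size_t i = 0; i < fout.size(); ++i)
    for (int k = 0; k < 3; ++k) fm(i, k) = remap[fout[i][k]];
  return List::create(_["vertices"] = vm, _["faces"] = fm);
}
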