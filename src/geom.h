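#ifndef CAVEX_GEOM_H
#define CAVEX_GEOM_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <array>
#include <limits>

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
  double operator[](int i) const { return i == 0 ? x : (i == 1 ? y : z); }
};

inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// det[b-a, c-a, d-a]; > 0 when d lies on the positive side of triangle (a,b,c)
inline double orient3d(const V3& a, const V3& b, const V3& c, const V3& d) {
  return dot(d - a, cross(b - a, c - a));
}

inline std::vector<V3> mat_to_pts(const Rcpp::NumericMatrix& m) {
  std::vector<V3> p(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) p[i] = V3(m(i, 0), m(i, 1), m(i, 2));
  return p;
}

// deterministic splitmix64 for seeded jitter / shuffles
inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
inline double unit_rand(uint64_t& s) {
  return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

// Moller-Trumbore segment/triangle intersection on t in [t0, t1];
// barycentric ties (ray through an edge/vertex) count as a hit.
inline bool seg_tri_hit(const V3& o, const V3& d, double t0, double t1,
                        const V3& a, const V3& b, const V3& c, double* t_out = nullptr) {
  const double tol = 1e-12;
  V3 e1 = b - a, e2 = c - a;
  V3 pv = cross(d, e2);
  double det = dot(e1, pv);
  double scale = norm(e1) * norm(e2) * norm(d);
  if (std::fabs(det) <= 1e-14 * scale) return false;  // parallel / degenerate
  double inv = 1.0 / det;
  V3 tv = o - a;
  double u = dot(tv, pv) * inv;
  if (u < -tol || u > 1.0 + tol) return false;
  V3 qv = cross(tv, e1);
  double v = dot(d, qv) * inv;
  if (v < -tol || u + v > 1.0 + tol) return false;
  double t = dot(e2, qv) * inv;
  if (t < t0 || t > t1) return false;
  if (t_out) *t_out = t;
  return true;
}

#endif
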