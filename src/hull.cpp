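#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;
  double nx, ny, nz, off;  // unit normal, plane offset (n . x = off)
  bool alive;
};

inline void plane_of(const std::vector<double>& px, const std::vector<double>& py,
                     const std::vector<double>& pz, Face& f) {
  const double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  const double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nn > 0) { nx /= nn; ny /= nn; nz /= nn; }
  f.nx = nx; f.ny = ny; f.nz = nz;
  f.off = nx * px[f.a] + ny * py[f.a] + nz * pz[f.a];
}

}  // namespace

// Incremental 3D convex hull of points in general position (callers jitter
// degenerate inputs). Returns hull triangles as one-based vertex indices,
// consistently oriented with outward normals.
// [[Rcpp::export]]
IntegerMatrix convhull3d(const NumericMatrix& pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    scale = std::max(scale, std::fabs(px[i]));
    scale = std::max(scale, std::fabs(py[i]));
    scale = std::max(scale, std::fabs(pz[i]));
  }
  const double eps = 1e-10 * (scale > 0 ? scale : 1.0);

  // initial simplex
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    const double dx = px[i] - px[i0], dy = py[i] - py[i0], dz = pz[i] - pz[i0];
    const double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps * eps) stop("degenerate input: points coincide");
  best = -1;
  const double ex = px[i1] - px[i0], ey = py[i1] - py[i0], ez = pz[i1] - pz[i0];
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    const double dx = px[i] - px[i0], dy = py[i] - py[i0], dz = pz[i] - pz[i0];
    const double cx = ey * dz - ez * dy, cy = ez * dx - ex * dz, cz = ex * dy - ey * dx;
    const double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * eps) stop("degenerate input: points collinear");
  Face f0{i0, i1, i2, 0, 0, 0, 0, true};
  plane_of(px, py, pz, f0);
  best = -1;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    const double d = std::fabs(f0.nx * px[i] + f0.ny * py[i] + f0.nz * pz[i] - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate input: points coplanar");

  std::vector<Face> faces;
  faces.reserve(8 * n);
  auto add_face = [&](int a, int b, int c, int opposite) {
    Face f{a, b, c, 0, 0, 0, 0, true};
    plane_of(px, py, pz, f);
    const double d = f.nx * px[opposite] + f.ny * py[opposite] + f.nz * pz[opposite] - f.off;
    if (d > 0) { std::swap(f.b, f.c); plane_of(px, py, pz, f); }
    faces.push_back(f);
  };
  add_face(i0, i1, i2, i3);
  add_face(i0, i1, i3, i2);
  add_face(i0, i2, i3, i1);
  add_face(i1, i2, i3, i0);

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    visible.clear();
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      const Face& f = faces[fi];
      if (!f.alive) continue;
      const double d = f.nx * px[p] + f.ny * py[p] + f.nz * pz[p] - f.off;
      if (d > eps) visible.push_back((int)fi);
    }
    if (visible.empty()) continue;  // interior point
    // collect directed edges of visible faces
    std::unordered_set<long long> dir_edges;
    dir_edges.reserve(visible.size() * 4);
    auto key = [n](int a, int b) { return (long long)a * (long long)n + b; };
    for (int fi : visible) {
      const Face& f = faces[fi];
      dir_edges.insert(key(f.a, f.b));
      dir_edges.insert(key(f.b, f.c));
      dir_edges.insert(key(f.c, f.a));
    }
    for (int fi : visible) faces[fi].alive = false;
    // horizon: directed edge whose reverse is not among visible faces' edges
    for (int fi : visible) {
      const Face f = faces[fi];
      const int ea[3] = {f.a, f.b, f.c};
      const int eb[3] = {f.b, f.c, f.a};
      for (int k = 0; k < 3; ++k) {
        if (dir_edges.find(key(eb[k], ea[k])) == dir_edges.end()) {
          Face nf{ea[k], eb[k], p, 0, 0, 0, 0, true};
          plane_of(px, py, pz, nf);
          faces.push_back(nf);
        }
      }
    }
    used[p] = 1;
  }

  int nf = 0;
  for (const Face& f : faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1; out(r, 1) = f.b + 1; out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}
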