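#include <Rcpp.h>
#include <array>
#include <cmath>
#include <map>
#include <tuple>
#include <vector>

using namespace Rcpp;

// Arrays are stored with dim = (nz, ny, nx): z fastest, then y, then x.
// Linear index of voxel (z, y, x), all 0-based: i = z + nz * (y + ny * x).

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> nb;  // (dz, dy, dx)
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dz, dy, dx});
      }

  int cur = 0;
  std::vector<R_xlen_t> todo;
  // Discovery raster order: row-major in the x-y plane (y, then x), then
  // depth. The first-encountered voxel of each component therefore follows
  // a top-left, row-major transect across the field of view.
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i] || labels[i]) continue;
        ++cur;
        todo.clear();
        todo.push_back(i);
        labels[i] = cur;
        while (!todo.empty()) {
          R_xlen_t j = todo.back();
          todo.pop_back();
          int zz = (int)(j % nz);
          R_xlen_t r = j / nz;
          int yy = (int)(r % ny);
          int xx = (int)(r / ny);
          for (const auto& o : nb) {
            int z2 = zz + o[0], y2 = yy + o[1], x2 = xx + o[2];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 ||
                x2 >= nx)
              continue;
            R_xlen_t k = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
            if (mask[k] && !labels[k]) {
              labels[k] = cur;
              todo.push_back(k);
            }
          }
        }
      }
  labels.attr("n_components") = cur;
  return labels;
}

namespace {

struct Welder {
  // Exact weld: crossing points lie on lattice edges; identical endpoint
  // ordering gives bit-identical coordinates, so keys quantised at 2^20
  // per micrometre are collision-safe for the stack sizes involved.
  std::map<std::tuple<long long, long long, long long>, int> seen;
  std::vector<double> vx, vy, vz;
  int add(double x, double y, double z) {
    const double s = 1048576.0;
    auto key = std::make_tuple((long long)std::llround(x * s),
                               (long long)std::llround(y * s),
                               (long long)std::llround(z * s));
    auto it = seen.find(key);
    if (it != seen.end()) return it->second;
    int id = (int)vx.size();
    seen.emplace(key, id);
    vx.push_back(x);
    vy.push_back(y);
    vz.push_back(z);
    return id;
  }
};

struct P3 {
  double x, y, z;
};

inline P3 cross3(const P3& a, const P3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}

}  // namespace

// Marching tetrahedra on the Kuhn 6-tet subdivision of each grid cell.
// field: scalar field sampled at voxel centres, dim (nz, ny, nx);
// spacing: (dx, dy, dz) in micrometres. Vertices are emitted in physical
// coordinates (x, y, z) = (ix * dx, iy * dy, iz * dz), 0-based indices.
// Triangles are oriented with outward normals (away from field > level).
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double level,
                    NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];

  // Kuhn subdivision: one tet per permutation of the unit steps.
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  Welder w;
  std::vector<int> tri;

  auto fidx = [&](int ix, int iy, int iz) -> R_xlen_t {
    return iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
  };

  // corner: integer coords (ix, iy, iz); value; global id for edge ordering
  struct Corner {
    int ix, iy, iz;
    double f;
    R_xlen_t gid;
  };

  auto interp = [&](const Corner& a, const Corner& b) -> int {
    // order endpoints deterministically so shared edges weld exactly
    const Corner* p = &a;
    const Corner* q = &b;
    if (p->gid > q->gid) std::swap(p, q);
    double t = (level - p->f) / (q->f - p->f);
    double X = (p->ix + t * (q->ix - p->ix)) * dx;
    double Y = (p->iy + t * (q->iy - p->iy)) * dy;
    double Z = (p->iz + t * (q->iz - p->iz)) * dz;
    return w.add(X, Y, Z);
  };

  auto emit = [&](int i0, int i1, int i2, const P3& inward) {
    if (i0 == i1 || i1 == i2 || i0 == i2) return;  // degenerate
    P3 a{w.vx[i0], w.vy[i0], w.vz[i0]};
    P3 b{w.vx[i1], w.vy[i1], w.vz[i1]};
    P3 c{w.vx[i2], w.vy[i2], w.vz[i2]};
    P3 u{b.x - a.x, b.y - a.y, b.z - a.z};
    P3 v{c.x - a.x, c.y - a.y, c.z - a.z};
    P3 n = cross3(u, v);
    double cx = (a.x + b.x + c.x) / 3.0 - inward.x;
    double cy = (a.y + b.y + c.y) / 3.0 - inward.y;
    double cz = (a.z + b.z + c.z) / 3.0 - inward.z;
    double d = n.x * cx + n.y * cy + n.z * cz;
    if (d >= 0) {
      tri.push_back(i0);
      tri.push_back(i1);
      tri.push_back(i2);
    } else {
      tri.push_back(i0);
      tri.push_back(i2);
      tri.push_back(i1);
    }
  };

  for (int ix = 0; ix + 1 < nx; ++ix)
    for (int iy = 0; iy + 1 < ny; ++iy)
      for (int iz = 0; iz + 1 < nz; ++iz) {
        // cell corner values; skip homogeneous cells fast
        double f8[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
          f8[c] = field[fidx(ix + ox, iy + oy, iz + oz)];
          (f8[c] >= level ? anyIn : anyOut) = true;
        }
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; ++t) {
          // walk (0,0,0) -> (1,1,1) adding axes in perms[t] order
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          off[1][perms[t][0]] = 1;
          off[2][perms[t][0]] = 1;
          off[2][perms[t][1]] = 1;

          Corner c[4];
          int nin = 0;
          bool in[4];
          for (int k = 0; k < 4; ++k) {
            c[k].ix = ix + off[k][0];
            c[k].iy = iy + off[k][1];
            c[k].iz = iz + off[k][2];
            c[k].f = f8[off[k][0] | (off[k][1] << 1) | (off[k][2] << 2)];
            c[k].gid = fidx(c[k].ix, c[k].iy, c[k].iz);
            in[k] = c[k].f >= level;
            if (in[k]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;

          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) (in[k] ? ins[ni++] : outs[no++]) = k;

          // reference point strictly inside the particle
          P3 ref{0, 0, 0};
          for (int k = 0; k < ni; ++k) {
            ref.x += c[ins[k]].ix * dx;
            ref.y += c[ins[k]].iy * dy;
            ref.z += c[ins[k]].iz * dz;
          }
          ref.x /= ni;
          ref.y /= ni;
          ref.z /= ni;

          if (nin == 1) {
            int a = ins[0];
            emit(interp(c[a], c[outs[0]]), interp(c[a], c[outs[1]]),
                 interp(c[a], c[outs[2]]), ref);
          } else if (nin == 3) {
            int a = outs[0];
            emit(interp(c[a], c[ins[0]]), interp(c[a], c[ins[1]]),
                 interp(c[a], c[ins[2]]), ref);
          } else {
            int a = ins[0], b = ins[1], p = outs[0], q = outs[1];
            int e0 = interp(c[a], c[p]);
            int e1 = interp(c[a], c[q]);
            int e2 = interp(c[b], c[q]);
            int e3 = interp(c[b], c[p]);
            emit(e0, e1, e2, ref);
            emit(e0, e2, e3, ref);
          }
        }
      }

  int nv = (int)w.vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = w.vx[i];
    V(i, 1) = w.vy[i];
    V(i, 2) = w.vz[i];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; ++i) {
    T(i, 0) = tri[3 * i] + 1;  // 1-based for R
    T(i, 1) = tri[3 * i + 1] + 1;
    T(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
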