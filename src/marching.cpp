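// Iso-surface extraction by marching tetrahedra over the Kuhn (Freudenthal)
// 6-tetrahedron decomposition of each cell.  The decomposition shares face
// diagonals between neighbouring cells, so the extracted surface is
// watertight by construction and free of the ambiguous cube configurations.
// Vertices are welded by lattice-edge identity.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based vertex indices, 3 per face
  std::unordered_map<uint64_t, int> edge_vertex;
};

// six tets sharing the 0-7 main diagonal; corner id bits = (x, y, z)
const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                        {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, IntegerVector dims, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = vol.begin();
  auto NODE = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  MeshAcc m;
  uint64_t nn = (uint64_t)nx * ny * nz;

  auto vertex_on_edge = [&](uint64_t a, uint64_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = a * nn + b;
    auto it = m.edge_vertex.find(key);
    if (it != m.edge_vertex.end()) return it->second;
    double va = v[a], vb = v[b];
    double t = (iso - va) / (vb - va);
    if (t < 1e-6) t = 1e-6;
    if (t > 1 - 1e-6) t = 1 - 1e-6;
    double ax = a % nx, ay = (a / nx) % ny, az = a / ((uint64_t)nx * ny);
    double bx = b % nx, by = (b / nx) % ny, bz = b / ((uint64_t)nx * ny);
    int id = (int)m.vx.size();
    m.vx.push_back(ax + t * (bx - ax));
    m.vy.push_back(ay + t * (by - ay));
    m.vz.push_back(az + t * (bz - az));
    m.edge_vertex.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c, double ox, double oy, double oz) {
    // orient so the normal points from inside (v > iso) to outside:
    // (ox,oy,oz) is a point on the outside; flip if normal points away from it
    double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
    double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
    double nxn = uy * wz - uz * wy, nyn = uz * wx - ux * wz, nzn = ux * wy - uy * wx;
    double cx = (m.vx[a] + m.vx[b] + m.vx[c]) / 3.0;
    double cy = (m.vy[a] + m.vy[b] + m.vy[c]) / 3.0;
    double cz = (m.vz[a] + m.vz[b] + m.vz[c]) / 3.0;
    double d = nxn * (ox - cx) + nyn * (oy - cy) + nzn * (oz - cz);
    if (d < 0) std::swap(b, c);
    m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
  };

  uint64_t corner[8];
  double px[8], py[8], pz[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          corner[c] = NODE(ci, cj, ck);
          px[c] = ci; py[c] = cj; pz[c] = ck;
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int q = 0; q < 4; ++q) {
            if (v[corner[T[q]]] > iso) in[nin++] = T[q];
            else out[nout++] = T[q];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int a = vertex_on_edge(corner[in[0]], corner[out[0]]);
            int b = vertex_on_edge(corner[in[0]], corner[out[1]]);
            int c = vertex_on_edge(corner[in[0]], corner[out[2]]);
            emit(a, b, c, px[out[0]], py[out[0]], pz[out[0]]);
          } else if (nin == 3) {
            int a = vertex_on_edge(corner[in[0]], corner[out[0]]);
            int b = vertex_on_edge(corner[in[1]], corner[out[0]]);
            int c = vertex_on_edge(corner[in[2]], corner[out[0]]);
            emit(a, b, c, px[out[0]], py[out[0]], pz[out[0]]);
          } else {  // 2 in, 2 out: a quad split into two triangles
            int a = vertex_on_edge(corner[in[0]], corner[out[0]]);
            int b = vertex_on_edge(corner[in[0]], corner[out[1]]);
            int c = vertex_on_edge(corner[in[1]], corner[out[1]]);
            int d = vertex_on_edge(corner[in[1]], corner[out[0]]);
            double ox = 0.5 * (px[out[0]] + px[out[1]]);
            double oy = 0.5 * (py[out[0]] + py[out[1]]);
            double oz = 0.5 * (pz[out[0]] + pz[out[1]]);
            emit(a, b, c, ox, oy, oz);
            emit(a, c, d, ox, oy, oz);
          }
        }
      }

  int nv = (int)m.vx.size();
  int nf = (int)m.tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int q = 0; q < nv; ++q) {
    verts(q, 0) = m.vx[q]; verts(q, 1) = m.vy[q]; verts(q, 2) = m.vz[q];
  }
  IntegerMatrix faces(nf, 3);
  for (int q = 0; q < nf; ++q) {
    faces(q, 0) = m.tri[3 * q] + 1;      // 1-based for R
    faces(q, 1) = m.tri[3 * q + 1] + 1;
    faces(q, 2) = m.tri[3 * q + 2] + 1;
  }
  return List::create(Named("vertices") = verts, Named("faces") = faces);
}
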