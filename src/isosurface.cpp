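#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

// Isosurface extraction from a binary voxel field at level 0.5.
//
// Each lattice cell is decomposed into six tetrahedra sharing the cell's
// main diagonal; every tetrahedron crossed by the 0.5 level set contributes
// one or two triangles whose vertices are edge midpoints (the level-0.5
// crossing of a 0/1 field under linear interpolation). The decomposition
// uses the same local diagonal in every cell, so shared cell faces are split
// identically on both sides and the extracted surface is watertight for any
// blob strictly inside the grid. Triangle orientation is fixed locally so
// normals point away from the inside (value-1) region.

namespace {

struct Key64Hash {
  std::size_t operator()(const uint64_t& k) const {
    return std::hash<uint64_t>()(k);
  }
};

// lattice corner offsets of a cell, standard ordering
const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

// six tetrahedra around the 0-6 diagonal
const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

} // namespace

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t nxy = (int64_t)nx * ny;
  auto at = [&](int i, int j, int k) -> bool {
    return mask[i + (int64_t)nx * j + nxy * k] != 0;
  };
  auto lin = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * j + (uint64_t)nxy * k;
  };

  std::unordered_map<uint64_t, int, Key64Hash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> faces; // triples of 0-based vertex ids

  const uint64_t NVOX = (uint64_t)nx * ny * nz;

  // midpoint vertex of the lattice edge (a,b); deduplicated by endpoint pair
  auto edge_vertex = [&](int ai, int aj, int ak, int bi, int bj, int bk) -> int {
    uint64_t a = lin(ai, aj, ak), b = lin(bi, bj, bk);
    if (a > b) std::swap(a, b);
    uint64_t key = a * NVOX + b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap.emplace(key, id);
    vx.push_back(0.5 * (ai + bi));
    vy.push_back(0.5 * (aj + bj));
    vz.push_back(0.5 * (ak + bk));
    return id;
  };

  // emit triangle (p,q,r), flipping if needed so the normal points from the
  // inside region toward ref with sign 'sgn' (+1: away from ref point which
  // lies inside; -1: toward ref point which lies outside)
  auto emit = [&](int p, int q, int r, double refx, double refy, double refz,
                  int sgn) {
    double ux = vx[q] - vx[p], uy = vy[q] - vy[p], uz = vz[q] - vz[p];
    double wx = vx[r] - vx[p], wy = vy[r] - vy[p], wz = vz[r] - vz[p];
    double nxx = uy * wz - uz * wy;
    double nyy = uz * wx - ux * wz;
    double nzz = ux * wy - uy * wx;
    double cx = (vx[p] + vx[q] + vx[r]) / 3.0 - refx;
    double cy = (vy[p] + vy[q] + vy[r]) / 3.0 - refy;
    double cz = (vz[p] + vz[q] + vz[r]) / 3.0 - refz;
    double d = nxx * cx + nyy * cy + nzz * cz;
    if (d * sgn < 0) std::swap(q, r);
    faces.push_back(p); faces.push_back(q); faces.push_back(r);
  };

  int ci[4], cj[4], ck[4];
  bool in[4];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 corners equal
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          bool v = at(i + CX[c], j + CY[c], k + CZ[c]);
          any = any || v; all = all && v;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            int corner = TETS[t][c];
            ci[c] = i + CX[corner]; cj[c] = j + CY[corner]; ck[c] = k + CZ[corner];
            in[c] = at(ci[c], cj[c], ck[c]);
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // apex = the lone inside (nin==1) or lone outside (nin==3) vertex
            int a = 0;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) { a = c; break; }
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            int p = edge_vertex(ci[a], cj[a], ck[a], ci[o[0]], cj[o[0]], ck[o[0]]);
            int q = edge_vertex(ci[a], cj[a], ck[a], ci[o[1]], cj[o[1]], ck[o[1]]);
            int r = edge_vertex(ci[a], cj[a], ck[a], ci[o[2]], cj[o[2]], ck[o[2]]);
            emit(p, q, r, ci[a], cj[a], ck[a], nin == 1 ? +1 : -1);
          } else { // 2 in, 2 out: quad split into two triangles
            int ina[2], outa[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) ina[mi++] = c; else outa[mo++] = c;
            }
            int v00 = edge_vertex(ci[ina[0]], cj[ina[0]], ck[ina[0]],
                                  ci[outa[0]], cj[outa[0]], ck[outa[0]]);
            int v01 = edge_vertex(ci[ina[0]], cj[ina[0]], ck[ina[0]],
                                  ci[outa[1]], cj[outa[1]], ck[outa[1]]);
            int v10 = edge_vertex(ci[ina[1]], cj[ina[1]], ck[ina[1]],
                                  ci[outa[0]], cj[outa[0]], ck[outa[0]]);
            int v11 = edge_vertex(ci[ina[1]], cj[ina[1]], ck[ina[1]],
                                  ci[outa[1]], cj[outa[1]], ck[outa[1]]);
            double rx = 0.5 * (ci[ina[0]] + ci[ina[1]]);
            double ry = 0.5 * (cj[ina[0]] + cj[ina[1]]);
            double rz = 0.5 * (ck[ina[0]] + ck[ina[1]]);
            // quad v00-v01-v11-v10 (v00,v01 share inside vertex 0; crossing
            // to v11,v10 keeps adjacency): split along v00-v11
            emit(v00, v01, v11, rx, ry, rz, +1);
            emit(v00, v11, v10, rx, ry, rz, +1);
          }
        }
      }
    }
  }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v];
  }
  int nf = (int)faces.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = faces[3 * f] + 1;
    F(f, 1) = faces[3 * f + 1] + 1;
    F(f, 2) = faces[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nbr.push_back({dx, dy, dz});
      }

  int next_label = 0;
  std::queue<int64_t> q;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      int64_t cur = q.front(); q.pop();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((int64_t)nx * ny));
      for (const auto& d : nbr) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int64_t t = ii + (int64_t)nx * jj + (int64_t)nx * ny * kk;
        if (mask[t] && labels[t] == 0) {
          labels[t] = next_label;
          q.push(t);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
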