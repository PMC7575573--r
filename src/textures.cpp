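#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as R arrays in column-major order; level 0 marks
// out-of-mask voxels, in-mask voxels carry discretized levels 1..ng.

static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

inline int vox(const IntegerVector& lv, int x, int y, int z,
               int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return lv[x + nx * (y + ny * z)];
}

// Symmetric co-occurrence counts at Chebyshev distance 1, one ng x ng slab
// per unique 3D direction.
// [[Rcpp::export]]
IntegerVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(ng * ng * NDIR);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    int base = ng * ng * d;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = vox(levels, x, y, z, nx, ny, nz);
          if (a == 0) continue;
          int b = vox(levels, x + dx, y + dy, z + dz, nx, ny, nz);
          if (b == 0) continue;
          out[base + (a - 1) + ng * (b - 1)] += 1;
          out[base + (b - 1) + ng * (a - 1)] += 1;
        }
  }
  return out;
}

// Run-length counts per direction; returns ng x maxlen x 13.
// [[Rcpp::export]]
IntegerVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(std::max(nx, ny), nz);
  IntegerVector out(ng * maxlen * NDIR);
  for (int d = 0; d < NDIR; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    int base = ng * maxlen * d;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = vox(levels, x, y, z, nx, ny, nz);
          if (a == 0) continue;
          // start of a run only when the previous voxel along d differs
          if (vox(levels, x - dx, y - dy, z - dz, nx, ny, nz) == a) continue;
          int len = 1;
          while (vox(levels, x + len * dx, y + len * dy, z + len * dz,
                     nx, ny, nz) == a) ++len;
          out[base + (a - 1) + ng * (len - 1)] += 1;
        }
  }
  return out;
}

// Size zones by 26-connectivity flood fill; returns a 2-column matrix of
// (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlevel, zsize, stack;
  for (int i = 0; i < n; ++i) {
    if (levels[i] == 0 || seen[i]) continue;
    int lev = levels[i], size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
              continue;
            int j = x + nx * (y + ny * z);
            if (seen[j] || levels[j] != lev) continue;
            seen[j] = 1;
            stack.push_back(j);
          }
    }
    zlevel.push_back(lev);
    zsize.push_back(size);
  }
  IntegerMatrix out(zlevel.size(), 2);
  for (size_t k = 0; k < zlevel.size(); ++k) {
    out(k, 0) = zlevel[k];
    out(k, 1) = zsize[k];
  }
  return out;
}

// Neighborhood gray-tone difference: per level, voxel count n_i (voxels with
// >= 1 in-mask 26-neighbor) and summed absolute deviation s_i from the
// neighborhood mean; out-of-mask neighbors are excluded from the average.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(ng);
  IntegerVector cnt(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = vox(levels, x, y, z, nx, ny, nz);
        if (a == 0) continue;
        double sum = 0;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = vox(levels, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b > 0) { sum += b; ++k; }
            }
        if (k == 0) continue;
        s[a - 1] += std::fabs(a - sum / k);
        cnt[a - 1] += 1;
      }
  return List::create(_["s"] = s, _["n"] = cnt);
}

// Neighborhood gray-level dependence: counts of (level, number of 26-neighbors
// within +/- alpha of the center level); column k holds dependence k-1.
// [[Rcpp::export]]
IntegerMatrix cpp_ngldm(IntegerVector levels, IntegerVector dim, int ng,
                        int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = vox(levels, x, y, z, nx, ny, nz);
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = vox(levels, x + dx, y + dy, z + dz, nx, ny, nz);
              if (b > 0 && std::abs(b - a) <= alpha) ++dep;
            }
        out(a - 1, dep) += 1;
      }
  return out;
}
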