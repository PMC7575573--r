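#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Separable exact squared Euclidean distance transform (lower-envelope-of-
// parabolas algorithm), with an anisotropic per-axis sample spacing so
// distances come out in physical mm.

static void dt1d(std::vector<double>& f, double w2) {
  int n = f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  std::vector<double> d(n);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// Squared distance (mm^2) from every voxel center to the nearest foreground
// voxel center; foreground voxels get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  // large finite stand-in for +inf keeps the parabola intersections finite
  const double BIG = 1e20;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) line[x] = out[x + nx * (y + ny * z)];
      dt1d(line, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; ++x) out[x + nx * (y + ny * z)] = line[x];
    }
  // y pass
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = out[x + nx * (y + ny * z)];
      dt1d(line, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; ++y) out[x + nx * (y + ny * z)] = line[y];
    }
  // z pass
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = out[x + nx * (y + ny * z)];
      dt1d(line, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; ++z) out[x + nx * (y + ny * z)] = line[z];
    }
  return out;
}
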