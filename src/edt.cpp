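#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1D squared distance transform of a
// sampled function f (lower envelope of parabolas). In-place on d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest seed voxel (seed != 0). Grid is nx x ny x nz, column-major.
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector seed, int nx, int ny, int nz) {
  const double INF = 1e20;
  NumericVector out(nx * ny * nz);
  // init: 0 at seeds, INF elsewhere
  for (int i = 0; i < nx * ny * nz; i++) out[i] = seed[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(std::max(nx, std::max(ny, nz)));

  // pass along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      long base = (long)z * nx * ny + (long)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      long base = (long)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (long)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) out[base + (long)y * nx] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      long base = (long)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (long)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) out[base + (long)z * nx * ny] = d[z];
    }
  return out;
}
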