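#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Connected-component labelling of a 3D logical grid under 26-connectivity.
// Returns an integer grid of the same shape with components labelled densely
// from 1 in scan order (0 elsewhere).
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector flags, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;

  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!flags[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v % ((R_xlen_t)nx * ny));
      int y = rem / nx;
      int x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (flags[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

// One-dimensional squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012) with physical sample spacing `step`.
static void dt1d(std::vector<double>& f, double step, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else { break; }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance (physical units) from every voxel to the nearest
// background voxel (foreground = TRUE). Background voxels get 0; a grid with
// no background voxel gets Inf everywhere on the foreground. Voxels outside
// the grid are not considered background.
// [[Rcpp::export(name = ".distance_to_background")]]
NumericVector distance_to_background(LogicalVector foreground, IntegerVector dim,
                                     NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double BIG = 1e20;  // finite sentinel; squared distances stay << BIG
  NumericVector out(n);
  out.attr("dim") = dim;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = foreground[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x lines
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      f.assign(out.begin() + base, out.begin() + base + nx);
      dt1d(f, spacing[0], d, v, z);
      for (int xx = 0; xx < nx; ++xx) out[base + xx] = f[xx];
    }
  // y lines
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      f.resize(ny);
      for (int yy = 0; yy < ny; ++yy) f[yy] = out[base + (R_xlen_t)yy * nx];
      dt1d(f, spacing[1], d, v, z);
      for (int yy = 0; yy < ny; ++yy) out[base + (R_xlen_t)yy * nx] = f[yy];
    }
  // z lines
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      f.resize(nz);
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + (R_xlen_t)zz * nx * ny];
      dt1d(f, spacing[2], d, v, z);
      for (int zz = 0; zz < nz; ++zz) out[base + (R_xlen_t)zz * nx * ny] = f[zz];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= 1e19) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
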