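#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// construction (Felzenszwalb & Huttenlocher). BIG stands in for +Inf;
// safe while nmax^2 + BIG stays far below double overflow.
static const double BIG = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  NumericVector D(n);
  bool any_feature = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) { D[i] = 0.0; any_feature = true; } else D[i] = BIG;
  }
  if (!any_feature) stop("distance transform of an empty mask is undefined");

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (contiguous)
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx;
      for (int xi = 0; xi < nx; ++xi) f[xi] = D[base + xi];
      dt1d(f, d, nx, v, z);
      for (int xi = 0; xi < nx; ++xi) D[base + xi] = d[xi];
    }
  // pass along y (stride nx)
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + xi;
      for (int yi = 0; yi < ny; ++yi) f[yi] = D[base + (R_xlen_t)yi * nx];
      dt1d(f, d, ny, v, z);
      for (int yi = 0; yi < ny; ++yi) D[base + (R_xlen_t)yi * nx] = d[yi];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int yi = 0; yi < ny; ++yi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = (R_xlen_t)yi * nx + xi;
      for (int zi = 0; zi < nz; ++zi) f[zi] = D[base + (R_xlen_t)zi * sxy];
      dt1d(f, d, nz, v, z);
      for (int zi = 0; zi < nz; ++zi) D[base + (R_xlen_t)zi * sxy] = d[zi];
    }
  return D;
}

// 26-connected boundary of every positive label: a voxel belongs to the
// boundary of its label when any of its 26 neighbours carries a different
// label; voxels on the volume face count as boundary (outside = background).
//' @noRd
// [[Rcpp::export(name = ".label_boundary")]]
LogicalVector label_boundary(IntegerVector lab, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (lab.size() != n) stop("label length does not match dims");
  LogicalVector out(n);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi)
      for (int xi = 0; xi < nx; ++xi) {
        R_xlen_t idx = (R_xlen_t)zi * sxy + (R_xlen_t)yi * nx + xi;
        int l = lab[idx];
        if (l <= 0) { out[idx] = false; continue; }
        bool bdry = false;
        for (int dz = -1; dz <= 1 && !bdry; ++dz)
          for (int dy = -1; dy <= 1 && !bdry; ++dy)
            for (int dx = -1; dx <= 1 && !bdry; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = xi + dx, y2 = yi + dy, z2 = zi + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz) { bdry = true; break; }
              if (lab[(R_xlen_t)z2 * sxy + (R_xlen_t)y2 * nx + x2] != l) {
                bdry = true; break;
              }
            }
        out[idx] = bdry;
      }
  return out;
}
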