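#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3-D logical grid (face, edge or
// corner adjacency joins voxels).  A grid with one singleton dimension
// degenerates to 8-connectivity in-plane.  Labels are assigned in raster
// (column-major) order of each component's first voxel; callers re-order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector& fg,
                                   const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("foreground length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!fg[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (fg[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 3x3x3 box (mean) filter with zero padding outside the grid; used to
// regularize the binary indicator before surface meshing.
// [[Rcpp::export]]
NumericVector smooth_box3_cpp(const NumericVector& f,
                              const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              s += f[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            }
          }
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = s / 27.0;
      }
  return out;
}
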