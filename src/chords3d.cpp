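#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a scalar field sampled at voxel centers
// (center of voxel (i,j,k), 1-based, lies at ((i-1)sx, (j-1)sy, (k-1)sz)
// mm).  Points outside the sampled lattice read as 0 (background).
static double trilinear(double x, double y, double z, const NumericVector& f,
                        int nx, int ny, int nz,
                        double sx, double sy, double sz) {
  double gx = x / sx, gy = y / sy, gz = z / sz;
  if (gx < -1 || gy < -1 || gz < -1 || gx > nx || gy > ny || gz > nz) return 0.0;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  double val = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = ix + dx, yy = iy + dy, zz = iz + dz;
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        if (w == 0.0) continue;
        double v = 0.0;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = f[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        val += w * v;
      }
  return val;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(const NumericMatrix& pts, const NumericVector& f,
                            const IntegerVector& dims, const NumericVector& spacing) {
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = trilinear(pts(i, 0), pts(i, 1), pts(i, 2), f,
                       dims[0], dims[1], dims[2],
                       spacing[0], spacing[1], spacing[2]);
  return out;
}

// Interior containment of a 3-D segment: trilinear value >= level at all
// midpoint samples t=(i-0.5)/n, n = ceil(len/step).
static bool chord_contained3d(double ax, double ay, double az,
                              double bx, double by, double bz,
                              const NumericVector& f, int nx, int ny, int nz,
                              double sx, double sy, double sz,
                              double step, double level) {
  double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay) +
                         (bz - az) * (bz - az));
  int n = (int)std::ceil(len / step);
  if (n < 1) n = 1;
  for (int i = 1; i <= n; ++i) {
    double t = (i - 0.5) / n;
    if (trilinear(ax + t * (bx - ax), ay + t * (by - ay), az + t * (bz - az),
                  f, nx, ny, nz, sx, sy, sz) < level) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector chord_contained3d_cpp(const NumericMatrix& seg, const NumericVector& f,
                                    const IntegerVector& dims, const NumericVector& spacing,
                                    double step, double level) {
  LogicalVector out(seg.nrow());
  for (int i = 0; i < seg.nrow(); ++i)
    out[i] = chord_contained3d(seg(i, 0), seg(i, 1), seg(i, 2),
                               seg(i, 3), seg(i, 4), seg(i, 5),
                               f, dims[0], dims[1], dims[2],
                               spacing[0], spacing[1], spacing[2], step, level);
  return out;
}

struct PairRec3 {
  double len;
  int i, j;
};

// Exhaustive contained longest-3D-diameter search over candidate endpoints
// (mm coordinates).  Decreasing-length scan with tie collection, as in the
// 2-D search.  Returns columns: i, j, length (1-based indices).
// [[Rcpp::export]]
NumericMatrix longest_chord3d_cpp(const NumericMatrix& pts, const NumericVector& f,
                                  const IntegerVector& dims, const NumericVector& spacing,
                                  double step, double level, double tie_eps) {
  const int n = pts.nrow();
  std::vector<PairRec3> pairs;
  pairs.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - pts(i, 0), dy = pts(j, 1) - pts(i, 1),
             dz = pts(j, 2) - pts(i, 2);
      double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len > 0) pairs.push_back(PairRec3{len, i, j});
    }
  std::sort(pairs.begin(), pairs.end(), [](const PairRec3& a, const PairRec3& b) {
    if (a.len != b.len) return a.len > b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<PairRec3> hits;
  double best = -1.0;
  for (size_t k = 0; k < pairs.size(); ++k) {
    if (best >= 0 && pairs[k].len < best - tie_eps) break;
    if (chord_contained3d(pts(pairs[k].i, 0), pts(pairs[k].i, 1), pts(pairs[k].i, 2),
                          pts(pairs[k].j, 0), pts(pairs[k].j, 1), pts(pairs[k].j, 2),
                          f, dims[0], dims[1], dims[2],
                          spacing[0], spacing[1], spacing[2], step, level)) {
      if (best < 0) best = pairs[k].len;
      hits.push_back(pairs[k]);
    }
  }
  NumericMatrix out(hits.size(), 3);
  for (size_t k = 0; k < hits.size(); ++k) {
    out(k, 0) = hits[k].i + 1;
    out(k, 1) = hits[k].j + 1;
    out(k, 2) = hits[k].len;
  }
  return out;
}
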