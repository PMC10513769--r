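#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iso-surface area by marching tetrahedra: each lattice cell (8 voxel
// centers) is split into 6 tetrahedra around the main diagonal, and the
// level-set crossing of every tetrahedron contributes 0, 1 or 2 triangles
// with vertices linearly interpolated along the edges.  The caller pads
// the field with a background layer so the surface is closed.

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
// cube corner offsets, index bit order (x, y, z)
static const int CO[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

static inline void interp(const double* p, const double* q, double vp, double vq,
                          double level, double* out) {
  double t = (level - vp) / (vq - vp);
  for (int d = 0; d < 3; ++d) out[d] = p[d] + t * (q[d] - p[d]);
}

static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3], v[3];
  for (int d = 0; d < 3; ++d) {
    u[d] = b[d] - a[d];
    v[d] = c[d] - a[d];
  }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double mt_surface_area_cpp(const NumericVector& f, const IntegerVector& dims,
                           const NumericVector& spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0;
  double pos[4][3], val[4];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double cv[8];
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = f[(x + CO[c][0]) +
                    (R_xlen_t)nx * ((y + CO[c][1]) + (R_xlen_t)ny * (z + CO[c][2]))];
          (cv[c] > level ? any_hi : any_lo) = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4], na = 0, nb = 0;
          for (int k = 0; k < 4; ++k) {
            int c = TETS[t][k];
            pos[k][0] = (x + CO[c][0]) * sx;
            pos[k][1] = (y + CO[c][1]) * sy;
            pos[k][2] = (z + CO[c][2]) * sz;
            val[k] = cv[c];
            if (val[k] > level) above[na++] = k; else below[nb++] = k;
          }
          if (na == 0 || na == 4) continue;
          double a[3], b[3], c3[3], d3[3];
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            const int* rest = (na == 1) ? below : above;
            interp(pos[apex], pos[rest[0]], val[apex], val[rest[0]], level, a);
            interp(pos[apex], pos[rest[1]], val[apex], val[rest[1]], level, b);
            interp(pos[apex], pos[rest[2]], val[apex], val[rest[2]], level, c3);
            area += tri_area(a, b, c3);
          } else {  // 2-2: quad split into two triangles
            interp(pos[above[0]], pos[below[0]], val[above[0]], val[below[0]], level, a);
            interp(pos[above[0]], pos[below[1]], val[above[0]], val[below[1]], level, b);
            interp(pos[above[1]], pos[below[1]], val[above[1]], val[below[1]], level, c3);
            interp(pos[above[1]], pos[below[0]], val[above[1]], val[below[0]], level, d3);
            area += tri_area(a, b, c3) + tri_area(a, c3, d3);
          }
        }
      }
  return area;
}
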