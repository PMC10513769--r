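#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Even-odd (crossing number) point-in-region test against a set of closed
// rings (outer boundaries and holes of one in-plane region).  Rings are
// n x 2 matrices; the closing edge last->first is implicit.
static bool point_in_rings(double px, double py, const std::vector<NumericMatrix>& rings) {
  bool inside = false;
  for (size_t r = 0; r < rings.size(); ++r) {
    const NumericMatrix& m = rings[r];
    int n = m.nrow();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = m(i, 0), yi = m(i, 1), xj = m(j, 0), yj = m(j, 1);
      if ((yi > py) != (yj > py)) {
        double xcross = xj + (py - yj) / (yi - yj) * (xi - xj);
        if (px < xcross) inside = !inside;
      }
    }
  }
  return inside;
}

static std::vector<NumericMatrix> ring_list(const List& rings) {
  std::vector<NumericMatrix> v;
  for (R_xlen_t i = 0; i < rings.size(); ++i) v.push_back(as<NumericMatrix>(rings[i]));
  return v;
}

// [[Rcpp::export]]
LogicalVector point_in_rings_cpp(const NumericMatrix& pts, const List& rings) {
  std::vector<NumericMatrix> rs = ring_list(rings);
  LogicalVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = point_in_rings(pts(i, 0), pts(i, 1), rs);
  return out;
}

// Segment containment: interior samples at midpoint positions t=(i-0.5)/n,
// n = ceil(len/step), must all fall inside the region.  Endpoints are
// contour vertices and sit on the boundary by construction, so they are
// not sampled.
static bool chord_contained(double ax, double ay, double bx, double by,
                            const std::vector<NumericMatrix>& rings, double step) {
  double len = std::hypot(bx - ax, by - ay);
  int n = (int)std::ceil(len / step);
  if (n < 1) n = 1;
  for (int i = 1; i <= n; ++i) {
    double t = (i - 0.5) / n;
    if (!point_in_rings(ax + t * (bx - ax), ay + t * (by - ay), rings)) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector chord_contained2d_cpp(const NumericMatrix& seg, const List& rings,
                                    double step) {
  std::vector<NumericMatrix> rs = ring_list(rings);
  LogicalVector out(seg.nrow());
  for (int i = 0; i < seg.nrow(); ++i)
    out[i] = chord_contained(seg(i, 0), seg(i, 1), seg(i, 2), seg(i, 3), rs, step);
  return out;
}

struct PairRec {
  double len;
  int i, j;
};

// Exhaustive contained-chord search over contour vertices.  Pairs are
// scanned in decreasing length order; the first fully contained pair is
// maximal, and all contained pairs within tie_eps of it are returned
// (columns: i, j, length; 1-based indices) so the caller can apply
// secondary tie-breaks.  With `ref_dir`, only pairs whose undirected angle
// to ref_dir lies within 90 +/- tol_deg are candidates (perpendicular
// diameter search).
// [[Rcpp::export]]
NumericMatrix longest_chord2d_cpp(const NumericMatrix& verts, const List& rings,
                                  double step, Nullable<NumericVector> ref_dir,
                                  double tol_deg, double tie_eps) {
  std::vector<NumericMatrix> rs = ring_list(rings);
  const int n = verts.nrow();
  bool use_ref = ref_dir.isNotNull();
  double rx = 0, ry = 0, cos_lim = 0;
  if (use_ref) {
    NumericVector rd(ref_dir);
    double nr = std::hypot(rd[0], rd[1]);
    rx = rd[0] / nr;
    ry = rd[1] / nr;
    cos_lim = std::cos((90.0 - tol_deg) * M_PI / 180.0);
  }
  std::vector<PairRec> pairs;
  pairs.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    double xi = verts(i, 0), yi = verts(i, 1);
    for (int j = i + 1; j < n; ++j) {
      double dx = verts(j, 0) - xi, dy = verts(j, 1) - yi;
      double len = std::hypot(dx, dy);
      if (len <= 0) continue;
      if (use_ref) {
        double c = std::fabs((dx * rx + dy * ry) / len);
        if (c > cos_lim + 1e-12) continue;
      }
      pairs.push_back(PairRec{len, i, j});
    }
  }
  std::sort(pairs.begin(), pairs.end(), [](const PairRec& a, const PairRec& b) {
    if (a.len != b.len) return a.len > b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<PairRec> hits;
  double best = -1.0;
  for (size_t k = 0; k < pairs.size(); ++k) {
    if (best >= 0 && pairs[k].len < best - tie_eps) break;
    if (chord_contained(verts(pairs[k].i, 0), verts(pairs[k].i, 1),
                        verts(pairs[k].j, 0), verts(pairs[k].j, 1), rs, step)) {
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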