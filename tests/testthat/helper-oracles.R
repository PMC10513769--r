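# Independent brute-force oracles, written in plain R against the same
# geometric conventions as the package (0.5-level contours, midpoint
# containment sampling, even-odd polygon test, trilinear >= 0.5), but with
# no shared code path: straight scans over all candidate pairs.

# even-odd point-in-region test for a matrix of points against a list of
# closed rings (n x 2 matrices); vectorised over points x edges
pip_oracle <- function(pts, rings) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 1]
  py <- pts[, 2]
  for (m in rings) {
    n <- nrow(m)
    xi <- m[, 1]; yi <- m[, 2]
    xj <- m[c(n, seq_len(n - 1)), 1]; yj <- m[c(n, seq_len(n - 1)), 2]
    for (e in seq_len(n)) {
      straddle <- (yi[e] > py) != (yj[e] > py)
      if (any(straddle)) {
        xcross <- xj[e] + (py[straddle] - yj[e]) / (yi[e] - yj[e]) *
          (xi[e] - xj[e])
        inside[straddle] <- xor(inside[straddle], px[straddle] < xcross)
      }
    }
  }
  inside
}

chord_contained_oracle <- function(a, b, rings, step = 0.2) {
  len <- sqrt(sum((b - a)^2))
  n <- max(1L, ceiling(len / step))
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  all(pip_oracle(pts, rings))
}

# maximum fully contained vertex-pair chord; optionally restricted to the
# 90 +/- tol_deg window around ref_dir.  Scans pairs in decreasing length
# order, so the first contained pair is the maximum.
longest_chord_oracle <- function(rings, step = 0.2, ref_dir = NULL,
                                 tol_deg = 2) {
  verts <- do.call(rbind, rings)
  n <- nrow(verts)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- verts[ij[, 2], 1] - verts[ij[, 1], 1]
  dy <- verts[ij[, 2], 2] - verts[ij[, 1], 2]
  len <- sqrt(dx^2 + dy^2)
  keep <- len > 0
  if (!is.null(ref_dir)) {
    u <- ref_dir / sqrt(sum(ref_dir^2))
    cosang <- abs((dx * u[1] + dy * u[2]) / len)
    keep <- keep & cosang <= cos((90 - tol_deg) * pi / 180) + 1e-12
  }
  ij <- ij[keep, , drop = FALSE]
  len <- len[keep]
  for (k in order(-len)) {
    a <- verts[ij[k, 1], ]
    b <- verts[ij[k, 2], ]
    if (chord_contained_oracle(a, b, rings, step)) return(len[k])
  }
  NA_real_
}

# trilinear interpolation of a field sampled at voxel centres, vectorised
# over a matrix of mm points; outside the lattice reads as 0
trilinear_oracle <- function(pts, field, spacing) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(field)
  g <- sweep(pts, 2, spacing, "/")
  i0 <- floor(g)
  f <- g - i0
  val <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    idx <- i0 + rep(c(dx, dy, dz), each = nrow(pts)) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    v <- numeric(nrow(pts))
    v[ok] <- field[idx[ok, , drop = FALSE]]
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    val <- val + w * v
  }
  val
}

chord_contained3d_oracle <- function(a, b, field, spacing, step = 0.2) {
  len <- sqrt(sum((b - a)^2))
  n <- max(1L, ceiling(len / step))
  t <- (seq_len(n) - 0.5) / n
  pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
               a[3] + t * (b[3] - a[3]))
  all(trilinear_oracle(pts, field, spacing) >= 0.5)
}

longest_chord3d_oracle <- function(pts, field, spacing, step = 0.2) {
  n <- nrow(pts)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  len <- sqrt(rowSums((pts[ij[, 2], , drop = FALSE] -
                       pts[ij[, 1], , drop = FALSE])^2))
  for (k in order(-len)) {
    if (chord_contained3d_oracle(pts[ij[k, 1], ], pts[ij[k, 2], ],
                                 field, spacing, step))
      return(len[k])
  }
  NA_real_
}

# queue-based 26-neighbourhood flood fill
flood_fill_oracle <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  nxt <- 0L
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (start in seq_along(fg)) {
    if (!fg[start] || lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      vi <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.integer(vi), "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
        cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
      lin <- lin[fg[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      queue <- c(queue, lin)
    }
  }
  lab
}

# canonical form of a labelling: sorted list of sorted voxel-index sets
partition_signature <- function(lab) {
  comps <- unname(split(which(lab > 0L), lab[lab > 0L]))
  comps <- lapply(comps, function(x) unname(sort(x)))
  comps[order(vapply(comps, `[`, integer(1), 1))]
}
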