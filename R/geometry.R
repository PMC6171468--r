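# Low-level triangle geometry kernels, vectorized over triangles.  All
# distances are Euclidean point-to-primitive (not geodesic); coordinates are
# um throughout.  These kernels are deliberately free of spatial acceleration
# so they can serve as their own exhaustive reference; the mesh-level
# operations add axis-aligned-bounding-box pruning on top.

dot3 <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
norm3 <- function(a) sqrt(pmax(0, dot3(a, a)))

# closest point on segments (A,B) to a single point p; returns list(d2, pts)
point_segments_closest <- function(p, A, B) {
  AB <- B - A
  AP <- sweep(A, 2, p, function(a, b) b - a)  # p - A
  len2 <- dot3(AB, AB)
  t <- ifelse(len2 > 0, dot3(AP, AB) / len2, 0)
  t <- pmin(1, pmax(0, t))
  cl <- A + AB * t
  dp <- sweep(cl, 2, p, "-")
  list(d2 = dot3(dp, dp), pts = cl, t = t)
}

# Closest points on a triangle soup to one point.  V1, V2, V3: n x 3 vertex
# matrices of n triangles.  Exact: plane projection where the foot lies
# inside, otherwise the nearest edge.  Returns list(d2, pts).
point_triangles_closest <- function(p, V1, V2, V3) {
  E0 <- V2 - V1
  E1 <- V3 - V1
  nrm <- cross3(E0, E1)
  n2 <- dot3(nrm, nrm)
  w <- sweep(V1, 2, p, function(a, b) b - a)  # p - V1
  dist_plane <- dot3(w, nrm) / sqrt(ifelse(n2 > 0, n2, 1))
  offset <- nrm * (dot3(w, nrm) / ifelse(n2 > 0, n2, 1))
  proj <- -sweep(offset, 2, p, "-")  # p - offset: projection of p onto plane
  # barycentric coordinates of the projected point
  vp <- proj - V1
  d00 <- dot3(E0, E0); d01 <- dot3(E0, E1); d11 <- dot3(E1, E1)
  d20 <- dot3(vp, E0); d21 <- dot3(vp, E1)
  den <- d00 * d11 - d01 * d01
  den_ok <- den > 0
  u <- ifelse(den_ok, (d11 * d20 - d01 * d21) / ifelse(den_ok, den, 1), -1)
  v <- ifelse(den_ok, (d00 * d21 - d01 * d20) / ifelse(den_ok, den, 1), -1)
  inside <- den_ok & u >= 0 & v >= 0 & (u + v) <= 1
  d2 <- numeric(nrow(V1))
  pts <- matrix(NA_real_, nrow(V1), 3)
  if (any(inside)) {
    d2[inside] <- dist_plane[inside]^2
    pts[inside, ] <- proj[inside, , drop = FALSE]
  }
  if (any(!inside)) {
    i <- which(!inside)
    e1 <- point_segments_closest(p, V1[i, , drop = FALSE], V2[i, , drop = FALSE])
    e2 <- point_segments_closest(p, V2[i, , drop = FALSE], V3[i, , drop = FALSE])
    e3 <- point_segments_closest(p, V3[i, , drop = FALSE], V1[i, , drop = FALSE])
    dmat <- cbind(e1$d2, e2$d2, e3$d2)
    pick <- max.col(-dmat, ties.method = "first")
    d2[i] <- dmat[cbind(seq_along(i), pick)]
    pmat <- rbind(e1$pts, e2$pts, e3$pts)
    pts[i, ] <- pmat[(pick - 1L) * length(i) + seq_along(i), , drop = FALSE]
  }
  list(d2 = d2, pts = pts)
}

# Minimum squared distance between two segments (scalar, Eberly-style).
seg_seg_dist2 <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-300 && e <= 1e-300) return(sum(r * r))
  if (a <= 1e-300) {
    s <- 0; t <- min(1, max(0, f / e))
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-300) {
      t <- 0; s <- min(1, max(0, -c_ / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 0) min(1, max(0, (b * f - c_ * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(1, max(0, -c_ / a)) }
      else if (t > 1) { t <- 1; s <- min(1, max(0, (b - c_) / a)) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sum(v * v)
}

# Exact minimum distance between two triangles (3x3 vertex matrices).
tri_tri_dist <- function(T1, T2) {
  d2 <- Inf
  # vertices of one against the other triangle
  for (i in 1:3) {
    r <- point_triangles_closest(T1[i, ], T2[1, , drop = FALSE],
                                 T2[2, , drop = FALSE], T2[3, , drop = FALSE])
    d2 <- min(d2, r$d2)
    r <- point_triangles_closest(T2[i, ], T1[1, , drop = FALSE],
                                 T1[2, , drop = FALSE], T1[3, , drop = FALSE])
    d2 <- min(d2, r$d2)
  }
  # edge pairs
  e1 <- list(c(1, 2), c(2, 3), c(3, 1))
  for (i in e1) for (j in e1) {
    d2 <- min(d2, seg_seg_dist2(T1[i[1], ], T1[i[2], ], T2[j[1], ], T2[j[2], ]))
  }
  sqrt(d2)
}

# Moller-Trumbore ray/triangle intersection, vectorized over triangles.
# Returns the smallest hit parameter t in (t_min, t_max) and its triangle
# index, or Inf/NA when nothing is hit.
ray_triangles <- function(orig, dir, V1, V2, V3, t_min = 1e-9, t_max = Inf) {
  E1 <- V2 - V1
  E2 <- V3 - V1
  dirm <- matrix(dir, nrow(V1), 3, byrow = TRUE)
  pvec <- cross3(dirm, E2)
  det <- dot3(E1, pvec)
  ok <- abs(det) > 1e-12
  tvec <- sweep(-V1, 2, orig, function(a, b) a + b)  # orig - V1
  u <- ifelse(ok, dot3(tvec, pvec) / ifelse(ok, det, 1), -1)
  qvec <- cross3(tvec, E1)
  v <- ifelse(ok, dot3(dirm, qvec) / ifelse(ok, det, 1), -1)
  t <- ifelse(ok, dot3(E2, qvec) / ifelse(ok, det, 1), Inf)
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > t_min & t < t_max
  t[!hit] <- Inf
  idx <- which.min(t)
  if (!length(idx) || is.infinite(t[idx]))
    list(t = Inf, tri = NA_integer_, any = FALSE)
  else
    list(t = t[idx], tri = idx, any = TRUE)
}
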