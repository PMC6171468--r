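# Labeled triangle surface meshes: container, validation, derived geometry,
# primitive generators and point-to-mesh distance queries.  Vertices are um;
# triangles are 1-based index triples wound counter-clockwise seen from
# outside (outward normals).

MESH_CLASSES <- c("axon", "bouton", "spine", "dendrite", "astrocyte",
                  "ER", "mitochondrion", "synapse", "vessel")

#' Allowed mesh class labels
#' @return character vector of the recognized neuropil/organelle classes.
#' @export
mesh_classes <- function() MESH_CLASSES

#' Construct and validate a surface mesh
#'
#' @param vertices n x 3 numeric matrix (um).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise from outside.
#' @param class class label, one of [mesh_classes()].
#' @param id integer object id (unique within a scene).
#' @param validate run full validation (degenerate faces, index range,
#'   consistent winding).
#' @return object of class `surface_mesh`; the `watertight` field is
#'   computed during validation.
#' @export
surface_mesh <- function(vertices, faces, class = "axon", id = 1L,
                         validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!class %in% MESH_CLASSES)
    stop("unknown mesh class '", class, "'; allowed: ",
         paste(MESH_CLASSES, collapse = ", "))
  m <- structure(list(vertices = vertices, faces = faces,
                      class = class, id = as.integer(id),
                      watertight = NA),
                 class = "surface_mesh")
  if (validate) m <- validate_mesh(m)
  m
}

#' Validate a surface mesh
#'
#' Checks: finite coordinates; indices in range; no degenerate (zero-area)
#' triangles; each directed edge used at most once (consistent winding); and
#' records watertightness (every undirected edge shared by exactly two
#' faces).
#'
#' @param m a `surface_mesh`.
#' @return `m` with `watertight` filled in; errors name offending elements.
#' @export
validate_mesh <- function(m) {
  V <- m$vertices; F <- m$faces
  if (any(!is.finite(V))) stop("mesh ", m$id, ": non-finite vertex coordinates")
  if (nrow(F) < 1) stop("mesh ", m$id, ": no faces")
  if (any(F < 1L) || any(F > nrow(V)))
    stop("mesh ", m$id, ": face index out of range at face(s) ",
         paste(utils::head(which(apply(F < 1L | F > nrow(V), 1, any)), 5),
               collapse = ", "))
  ar <- tri_areas(m)
  if (any(ar <= 0))
    stop("mesh ", m$id, ": degenerate (zero-area) triangle(s) at face(s) ",
         paste(utils::head(which(ar <= 0), 5), collapse = ", "))
  # directed edge multiplicity: consistent winding uses each directed edge once
  de <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(de[, 1], de[, 2])
  if (anyDuplicated(key))
    stop("mesh ", m$id, ": inconsistent winding (repeated directed edge)")
  ue <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  m$watertight <- all(table(ue) == 2L)
  m
}

tri_vertices <- function(m) {
  list(V1 = m$vertices[m$faces[, 1], , drop = FALSE],
       V2 = m$vertices[m$faces[, 2], , drop = FALSE],
       V3 = m$vertices[m$faces[, 3], , drop = FALSE])
}

#' Triangle areas, centroids and normals of a mesh
#' @param m a `surface_mesh`.
#' @return `tri_areas`: numeric vector (um^2); `tri_centroids`: m x 3
#'   matrix; `face_normals`: m x 3 unit normals.
#' @export
tri_areas <- function(m) {
  tv <- tri_vertices(m)
  0.5 * norm3(cross3(tv$V2 - tv$V1, tv$V3 - tv$V1))
}

#' @rdname tri_areas
#' @export
tri_centroids <- function(m) {
  tv <- tri_vertices(m)
  (tv$V1 + tv$V2 + tv$V3) / 3
}

#' @rdname tri_areas
#' @export
face_normals <- function(m) {
  tv <- tri_vertices(m)
  n <- cross3(tv$V2 - tv$V1, tv$V3 - tv$V1)
  n / pmax(norm3(n), 1e-300)
}

#' Area-weighted vertex normals and one-ring vertex areas
#'
#' Vertex normals are the normalized area-weighted mean of incident face
#' normals; the vertex area is one third of the incident triangle area (the
#' barycentric one-ring share), which partitions the total surface area.
#'
#' @param m a `surface_mesh`.
#' @return list with `normals` (n x 3) and `areas` (length n, um^2).
#' @export
vertex_normals <- function(m) {
  fn <- face_normals(m)
  ar <- tri_areas(m)
  n <- nrow(m$vertices)
  nrm <- matrix(0, n, 3)
  area <- numeric(n)
  for (k in 1:3) {
    idx <- m$faces[, k]
    for (c in 1:3)
      nrm[, c] <- nrm[, c] + unname(tapply2(fn[, c] * ar, idx, n))
    area <- area + tapply2(ar / 3, idx, n)
  }
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  list(normals = nrm, areas = area)
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Total surface area of a mesh
#' @param m a `surface_mesh`.
#' @return area in um^2.
#' @export
mesh_area <- function(m) sum(tri_areas(m))

mesh_bbox <- function(m) {
  rbind(lo = apply(m$vertices, 2, min), hi = apply(m$vertices, 2, max))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> id ", x$id, " (", x$class, "): ",
      nrow(x$vertices), " vertices, ", nrow(x$faces), " faces, ",
      if (isTRUE(x$watertight)) "watertight" else "open", "\n", sep = "")
  invisible(x)
}

#' Distances from points to a mesh surface
#'
#' Exact point-to-triangle distances, minimized over all triangles of the
#' mesh, with axis-aligned bounding-box pruning per point.
#'
#' @param pts k x 3 matrix of query points (um).
#' @param m a `surface_mesh`.
#' @return list with `dist` (length k) and `closest` (k x 3 points on the
#'   surface).
#' @export
dist_points_mesh <- function(pts, m) {
  pts <- matrix(pts, ncol = 3)
  tv <- tri_vertices(m)
  tlo <- pmin(tv$V1, pmin(tv$V2, tv$V3))
  thi <- pmax(tv$V1, pmax(tv$V2, tv$V3))
  k <- nrow(pts)
  dist <- numeric(k)
  closest <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    p <- pts[i, ]
    # lower bound: distance to each triangle AABB
    dlo <- sweep(tlo, 2, p, function(a, b) pmax(a - b, 0))
    dhi <- sweep(thi, 2, p, function(a, b) pmax(b - a, 0))
    lb2 <- rowSums(pmax(dlo, dhi)^2)
    ord <- which(lb2 <= min(lb2) + 1e-12)
    best <- point_triangles_closest(p, tv$V1[ord, , drop = FALSE],
                                    tv$V2[ord, , drop = FALSE],
                                    tv$V3[ord, , drop = FALSE])
    d2 <- min(best$d2)
    cand <- which(lb2 < d2)
    if (length(cand) > length(ord)) {
      full <- point_triangles_closest(p, tv$V1[cand, , drop = FALSE],
                                      tv$V2[cand, , drop = FALSE],
                                      tv$V3[cand, , drop = FALSE])
      j <- which.min(full$d2)
      if (full$d2[j] < d2) {
        d2 <- full$d2[j]
        closest[i, ] <- full$pts[j, ]
      } else closest[i, ] <- best$pts[which.min(best$d2), ]
    } else closest[i, ] <- best$pts[which.min(best$d2), ]
    dist[i] <- sqrt(d2)
  }
  list(dist = dist, closest = closest)
}

# ---- primitive generators ------------------------------------------------

#' Mesh primitives: icosphere, capped tube, flat patch
#'
#' `icosphere()` subdivides an icosahedron (`20 * 4^subdiv` faces, e.g.
#' subdiv 3 = 1280) and projects onto the sphere.  `tube_mesh()` builds a
#' watertight capped cylinder from `p0` to `p1`.  `patch_mesh()` builds a
#' planar square grid in the xy-plane (normals +z), open by construction.
#'
#' @param center sphere center (um).
#' @param radius sphere/tube radius (um).
#' @param subdiv icosphere subdivision level (>= 0).
#' @param class,id passed to [surface_mesh()].
#' @return a `surface_mesh`.
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdiv = 2,
                      class = "bouton", id = 1L) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      V <<- rbind(V, (V[i, ] + V[j, ]) / 2)
      mid_cache[[key]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, "+")
  surface_mesh(V, F, class = class, id = id)
}

#' @rdname icosphere
#' @param p0,p1 tube axis endpoints (um).
#' @param n_seg ring discretization (>= 3).
#' @export
tube_mesh <- function(p0, p1, radius = 0.5, n_seg = 12, class = "axon",
                      id = 1L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("tube of zero length")
  w <- axis / len
  u <- if (abs(w[1]) < 0.9) cross3(matrix(w, 1), matrix(c(1, 0, 0), 1))
       else cross3(matrix(w, 1), matrix(c(0, 1, 0), 1))
  u <- u / norm3(u)
  v <- cross3(matrix(w, 1), u)
  ang <- 2 * pi * (0:(n_seg - 1)) / n_seg
  ring <- outer(cos(ang), as.vector(u)) + outer(sin(ang), as.vector(v))
  ring0 <- sweep(ring * radius, 2, p0, "+")
  ring1 <- sweep(ring * radius, 2, p1, "+")
  V <- rbind(ring0, ring1, p0, p1)
  c0 <- 2L * n_seg + 1L
  c1 <- 2L * n_seg + 2L
  i <- 1:n_seg
  j <- c(2:n_seg, 1L)
  F <- rbind(
    cbind(i, j, n_seg + j),            # side lower
    cbind(i, n_seg + j, n_seg + i),    # side upper
    cbind(c0, j, i),                   # bottom cap (outward -w)
    cbind(c1, n_seg + i, n_seg + j))   # top cap (outward +w)
  surface_mesh(V, F, class = class, id = id)
}

#' @rdname icosphere
#' @param side patch side length (um).
#' @param n_div grid divisions per side (faces = `2 * n_div^2`).
#' @param center_xy patch center in the xy-plane.
#' @param z patch height.
#' @export
patch_mesh <- function(side = 10, n_div = 20, center_xy = c(0, 0), z = 0,
                       class = "dendrite", id = 1L) {
  xs <- seq(-side / 2, side / 2, length.out = n_div + 1) + center_xy[1]
  ys <- seq(-side / 2, side / 2, length.out = n_div + 1) + center_xy[2]
  V <- cbind(rep(xs, times = n_div + 1), rep(ys, each = n_div + 1), z)
  idx <- function(i, j) (j - 1L) * (n_div + 1L) + i
  F <- matrix(0L, 0, 3)
  for (j in seq_len(n_div)) {
    i <- seq_len(n_div)
    F <- rbind(F,
               cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  surface_mesh(V, F, class = class, id = id)
}

#' @rdname icosphere
#' @param lo,hi opposite corners of an axis-aligned box (um).
#' @export
box_mesh <- function(lo = c(-1, -1, -1), hi = c(1, 1, 1),
                     class = "mitochondrion", id = 1L) {
  x <- c(lo[1], hi[1]); y <- c(lo[2], hi[2]); z <- c(lo[3], hi[3])
  V <- as.matrix(expand.grid(x = x, y = y, z = z))  # binary order: x fastest
  dimnames(V) <- NULL
  # 12 triangles, outward CCW winding (vertex ids per expand.grid order)
  F <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = lo
    c(2, 4, 8), c(2, 8, 6),   # x = hi
    c(1, 6, 5), c(1, 2, 6),   # y = lo
    c(3, 8, 4), c(3, 7, 8),   # y = hi
    c(1, 3, 4), c(1, 4, 2),   # z = lo
    c(5, 8, 7), c(5, 6, 8))   # z = hi
  surface_mesh(V, F, class = class, id = id)
}
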