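# Morphometric quantification on labeled meshes: nearest-neighbor granule
# tallies, contact surface areas, organelle minimum distances and planar
# cross sections.

#' Nearest-neighbor tally of granules over meshes
#'
#' Assigns every granule to the mesh with the smallest exact point-to-surface
#' distance (ties broken toward the lower object id) and tallies counts per
#' class and per object.  The full assignment table is returned for audit.
#'
#' @param granules a granule set: data.frame with columns `x`, `y`, `z`
#'   (um), `r` (radius, um) and optionally `host_id` (see
#'   [read_granules()]).
#' @param meshes list of `surface_mesh` objects.
#' @return list with `assignment` (data.frame: granule, object id, class,
#'   distance), `by_class` (named counts) and `by_object` (data.frame).
#' @export
nearest_element_tally <- function(granules, meshes) {
  if (!length(meshes)) stop("empty mesh list")
  validate_granules(granules)
  ids <- vapply(meshes, function(m) m$id, integer(1))
  ord <- order(ids)  # lower id wins exact ties via strict < below
  meshes <- meshes[ord]
  ids <- ids[ord]
  classes <- vapply(meshes, function(m) m$class, character(1))
  pts <- cbind(granules$x, granules$y, granules$z)
  n <- nrow(pts)
  best_d <- rep(Inf, n)
  best_i <- rep(NA_integer_, n)
  for (i in seq_along(meshes)) {
    d <- dist_points_mesh(pts, meshes[[i]])$dist
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  assignment <- data.frame(
    granule = seq_len(n),
    object_id = ids[best_i],
    class = classes[best_i],
    distance = best_d
  )
  by_class <- table(factor(assignment$class, levels = sort(unique(classes))))
  by_object <- as.data.frame(table(object_id = assignment$object_id),
                             responseName = "count")
  by_object$object_id <- as.integer(as.character(by_object$object_id))
  by_object$class <- classes[match(by_object$object_id, ids)]
  list(assignment = assignment,
       by_class = c(by_class),
       by_object = by_object[, c("object_id", "class", "count")])
}

#' Contact surface area between two meshes
#'
#' Sum of the areas of `mesh_a` triangles whose centroid lies within
#' `epsilon` of `mesh_b`'s surface (exact point-to-triangle distance).
#' Measured on `mesh_a` by convention, so the operation is deliberately not
#' symmetric in its arguments.
#'
#' @param mesh_a,mesh_b `surface_mesh` objects.
#' @param epsilon proximity threshold (um, > 0).
#' @return contact area (um^2), with attribute `n_faces` (number of
#'   triangles counted).
#' @export
contact_area <- function(mesh_a, mesh_b, epsilon) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  cen <- tri_centroids(mesh_a)
  ar <- tri_areas(mesh_a)
  d <- dist_points_mesh(cen, mesh_b)$dist
  hit <- d <= epsilon
  structure(sum(ar[hit]), n_faces = sum(hit))
}

#' Minimum distance between two mesh surfaces
#'
#' Exact surface-to-surface minimum via triangle-triangle distances,
#' accelerated by a vertex-distance upper bound and per-triangle bounding-box
#' pruning; 0 if the meshes touch or intersect.
#'
#' @param mesh_a,mesh_b `surface_mesh` objects.
#' @return list with `distance` (um) and `points` (2 x 3 matrix: closest
#'   point on each mesh, from the vertex-stage estimate).
#' @export
min_distance <- function(mesh_a, mesh_b) {
  if (!nrow(mesh_a$faces) || !nrow(mesh_b$faces)) stop("empty mesh")
  # stage 1: vertices against the opposite surface (upper bound + points)
  ra <- dist_points_mesh(mesh_a$vertices, mesh_b)
  rb <- dist_points_mesh(mesh_b$vertices, mesh_a)
  ia <- which.min(ra$dist)
  ib <- which.min(rb$dist)
  if (ra$dist[ia] <= rb$dist[ib]) {
    ub <- ra$dist[ia]
    pts <- rbind(mesh_a$vertices[ia, ], ra$closest[ia, ])
  } else {
    ub <- rb$dist[ib]
    pts <- rbind(rb$closest[ib, ], mesh_b$vertices[ib, ])
  }
  # stage 2: exact triangle-triangle refinement on pairs whose boxes can beat
  # the bound (catches edge-edge minima between vertices)
  tva <- tri_vertices(mesh_a)
  tvb <- tri_vertices(mesh_b)
  lo_a <- pmin(tva$V1, pmin(tva$V2, tva$V3))
  hi_a <- pmax(tva$V1, pmax(tva$V2, tva$V3))
  lo_b <- pmin(tvb$V1, pmin(tvb$V2, tvb$V3))
  hi_b <- pmax(tvb$V1, pmax(tvb$V2, tvb$V3))
  best <- ub
  for (i in seq_len(nrow(mesh_a$faces))) {
    gap <- pmax(lo_b - rep(hi_a[i, ], each = nrow(lo_b)), 0) +
           pmax(rep(lo_a[i, ], each = nrow(lo_b)) - hi_b, 0)
    lb <- sqrt(rowSums(gap^2))
    cand <- which(lb < best)
    for (j in cand) {
      d <- tri_tri_dist(rbind(tva$V1[i, ], tva$V2[i, ], tva$V3[i, ]),
                        rbind(tvb$V1[j, ], tvb$V2[j, ], tvb$V3[j, ]))
      if (d < best) best <- d
    }
  }
  list(distance = best, points = pts)
}

#' Planar cross section of a watertight mesh
#'
#' Intersects the mesh with the plane through `point` with unit `normal`,
#' chains the triangle intersection segments into closed polygons and
#' returns their total area and perimeter.  A plane missing the mesh gives
#' `(0, 0)`; a non-watertight mesh is an error (an open section has no
#' well-defined area).
#'
#' @param m a watertight `surface_mesh`.
#' @param point a point on the cutting plane (um).
#' @param normal plane normal (need not be unit length).
#' @return list with `area` (um^2), `perimeter` (um) and `loops` (list of
#'   k x 2 polygon matrices in plane coordinates).
#' @export
cross_section_area <- function(m, point, normal) {
  if (!isTRUE(m$watertight))
    stop("cross section requires a watertight mesh (mesh ", m$id, " is open)")
  nrm <- normal / sqrt(sum(normal^2))
  sd <- as.vector(m$vertices %*% nrm) - sum(point * nrm)
  # avoid vertices exactly on the plane (degenerate chains): nudge them
  eps <- 1e-9 * max(1, max(abs(sd)))
  sd[sd == 0] <- eps
  f <- m$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossed <- !(sign(s1) == sign(s2) & sign(s2) == sign(s3))
  if (!any(crossed)) return(list(area = 0, perimeter = 0, loops = list()))
  # plane basis
  u <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- as.vector(cross3(matrix(nrm, 1), matrix(u, 1)))
  to2d <- function(P) cbind((P - matrix(point, nrow(P), 3, byrow = TRUE)) %*% u,
                            (P - matrix(point, nrow(P), 3, byrow = TRUE)) %*% v)
  # one segment per crossed triangle, keyed by the crossed (undirected) edges
  seg_from <- list(); seg_key <- list()
  edge_hit <- function(i, j) {
    a <- sd[i]; b <- sd[j]
    t <- a / (a - b)
    m$vertices[i, ] + t * (m$vertices[j, ] - m$vertices[i, ])
  }
  segs <- list()
  for (fi in which(crossed)) {
    vv <- f[fi, ]
    ss <- sd[vv]
    hits <- list(); keys <- character(0)
    pairs <- list(c(1, 2), c(2, 3), c(3, 1))
    for (pr in pairs) {
      if (sign(ss[pr[1]]) != sign(ss[pr[2]])) {
        hits[[length(hits) + 1]] <- edge_hit(vv[pr[1]], vv[pr[2]])
        keys <- c(keys, paste(min(vv[pr]), max(vv[pr])))
      }
    }
    if (length(hits) == 2)
      segs[[length(segs) + 1]] <- list(p = do.call(rbind, hits), k = keys)
  }
  if (!length(segs)) return(list(area = 0, perimeter = 0, loops = list()))
  # chain segments into loops by shared edge keys (watertight => 2 uses/key)
  n_seg <- length(segs)
  key_map <- new.env()
  for (i in seq_len(n_seg)) for (k in segs[[i]]$k)
    assign(k, c(if (exists(k, key_map, inherits = FALSE)) get(k, key_map), i),
           envir = key_map)
  used <- logical(n_seg)
  loops <- list()
  area <- 0; perim <- 0
  for (start in seq_len(n_seg)) {
    if (used[start]) next
    chain <- segs[[start]]$p[1, , drop = FALSE]
    cur <- start; cur_key <- segs[[start]]$k[2]
    pt <- segs[[start]]$p[2, ]
    used[start] <- TRUE
    repeat {
      chain <- rbind(chain, pt)
      nxt_candidates <- setdiff(get(cur_key, key_map), cur)
      nxt <- nxt_candidates[!used[nxt_candidates]]
      if (!length(nxt)) break
      cur <- nxt[1]
      used[cur] <- TRUE
      k2 <- segs[[cur]]$k
      if (k2[1] == cur_key) { pt <- segs[[cur]]$p[2, ]; cur_key <- k2[2] }
      else { pt <- segs[[cur]]$p[1, ]; cur_key <- k2[1] }
    }
    P <- to2d(chain)
    # drop the duplicated closing point if present
    if (nrow(P) > 1 && sum((P[1, ] - P[nrow(P), ])^2) < 1e-18)
      P <- P[-nrow(P), , drop = FALSE]
    if (nrow(P) >= 3) {
      xs <- P[, 1]; ys <- P[, 2]
      a2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) / 2
      area <- area + abs(a2)
      perim <- perim + sum(sqrt(rowSums((P - P[c(2:nrow(P), 1), ])^2)))
      loops[[length(loops) + 1]] <- P
    }
  }
  list(area = area, perimeter = perim, loops = loops)
}
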