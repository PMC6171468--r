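# Glycogen-derived lactate absorption maps (GLAM): glycogen granules are
# treated as isotropic point emitters and membrane meshes as receivers, in a
# radiance-transfer / photon-mapping analogy.  Two modes:
#   analytic    per-vertex irradiance  E_v = sum_i P_i cos(theta) V / (4 pi d^2)
#               with a binary ray-cast visibility term V against occluders;
#   montecarlo  isotropic photon emission, first-hit deposition, density
#               estimate over the one-ring vertex area; converges to the
#               unoccluded analytic map as the photon count grows.
# Absorbed power is in arbitrary units of emitted power per um^2.

#' Emission power of a glycogen granule
#'
#' Power proportional to granule volume: `P = k * (4/3) * pi * r^3`.  The
#' source of the proportionality is a modeling choice (granule content scales
#' with volume); `k` is configurable.
#'
#' @param radius granule radius (um, >= 0); vectorized.
#' @param k power coefficient (emitted power per um^3).
#' @return emission power (arbitrary units).
#' @export
granule_power <- function(radius, k = 1) {
  if (any(radius < 0)) stop("granule radius must be >= 0")
  k * (4 / 3) * pi * radius^3
}

#' Absorption map of glycogen granules on target meshes
#'
#' Computes a per-vertex absorbed-power-per-area scalar field on each target
#' mesh from a set of granule emitters.
#'
#' In analytic mode each vertex receives
#' `P_i * max(cos theta, 0) / (4 pi d^2)` from granule `i`, where `theta` is
#' measured against the vertex normal, optionally multiplied by a binary
#' visibility from ray casting against the occluder set.  In Monte Carlo
#' mode each granule emits `n_photons` isotropic photons carrying
#' `P_i / n_photons`; a photon deposits its power at the nearest vertex of
#' the first triangle it hits (targets and occluders both block), and vertex
#' totals are divided by the one-ring vertex area.
#'
#' @param targets list of `surface_mesh` receivers.
#' @param granules granule data.frame (`x`, `y`, `z`, `r`, optional
#'   `host_id`).
#' @param mode "analytic" or "montecarlo".
#' @param occlusion apply occlusion (analytic mode only; Monte Carlo photons
#'   are always blocked by whatever they hit first).
#' @param occluders list of meshes that block light (default: the targets
#'   themselves; granule host membranes should be excluded by the caller,
#'   since granules are intracellular and their light must exit the host).
#' @param n_photons photons per granule (Monte Carlo).
#' @param seed RNG seed (Monte Carlo; required for reproducibility).
#' @param k power coefficient, see [granule_power()].
#' @return list of `absorption_map` objects (one per target): list with
#'   `values` (per-vertex scalar), `mesh`, `mode`, `occlusion`, `n_photons`,
#'   `seed`, plus `se` (standard errors) and `hits` in Monte Carlo mode.
#' @export
absorption_map <- function(targets, granules, mode = c("analytic", "montecarlo"),
                           occlusion = FALSE, occluders = NULL,
                           n_photons = 1e4, seed = NULL, k = 1) {
  mode <- match.arg(mode)
  if (inherits(targets, "surface_mesh")) targets <- list(targets)
  validate_granules(granules)
  if (mode == "montecarlo") {
    if (n_photons < 1) stop("montecarlo mode needs n_photons >= 1")
    if (is.null(seed)) stop("montecarlo mode needs an explicit seed")
  }
  if (is.null(occluders)) occluders <- if (occlusion || mode == "montecarlo")
    targets else list()
  P <- granule_power(granules$r, k = k)
  centers <- cbind(granules$x, granules$y, granules$z)
  # granules must not lie exactly on a target surface
  for (m in targets) {
    d <- dist_points_mesh(centers, m)$dist
    if (any(d < 1e-9))
      stop("granule(s) ", paste(which(d < 1e-9), collapse = ", "),
           " lie exactly on the surface of mesh ", m$id)
  }
  if (mode == "analytic")
    lapply(targets, glam_analytic, centers = centers, P = P,
           occlusion = occlusion, occluders = occluders)
  else
    glam_montecarlo(targets, centers, P, occluders, n_photons, seed)
}

glam_analytic <- function(target, centers, P, occlusion, occluders) {
  vn <- vertex_normals(target)
  if (any(vn$areas <= 0)) stop("zero-area one-ring on mesh ", target$id)
  V <- target$vertices
  nv <- nrow(V)
  vals <- numeric(nv)
  occ <- if (occlusion)
    lapply(occluders, function(m) tri_vertices(m)) else list()
  occ_ids <- if (occlusion) vapply(occluders, `[[`, integer(1), "id") else integer(0)
  for (g in seq_len(nrow(centers))) {
    if (P[g] == 0) next
    dvec <- sweep(V, 2, centers[g, ], "-") * -1  # vertex -> granule
    d2 <- rowSums(dvec^2)
    d <- sqrt(d2)
    cosv <- pmax(0, rowSums(vn$normals * dvec) / pmax(d, 1e-300))
    contrib <- P[g] * cosv / (4 * pi * d2)
    if (occlusion && length(occ)) {
      for (i in which(contrib > 0)) {
        dir <- dvec[i, ] / d[i]
        for (oi in seq_along(occ)) {
          tv <- occ[[oi]]
          # skip self-shadowing of the receiving vertex itself on its own mesh
          hit <- ray_triangles(V[i, ], dir, tv$V1, tv$V2, tv$V3,
                               t_min = 1e-6 * d[i], t_max = d[i] * (1 - 1e-6))
          if (hit$any) { contrib[i] <- 0; break }
        }
      }
    }
    vals <- vals + contrib
  }
  structure(list(values = vals, mesh = target, mode = "analytic",
                 occlusion = occlusion, n_photons = NA, seed = NA),
            class = "absorption_map")
}

glam_montecarlo <- function(targets, centers, P, occluders, n_photons, seed) {
  # all blocking geometry in one soup; track which target (if any) owns each
  # triangle for deposition
  soup <- list(); owner <- integer(0); face_of <- integer(0)
  blockers <- targets
  extra <- occluders[!vapply(occluders, function(m)
    any(vapply(targets, function(t) identical(t, m), logical(1))), logical(1))]
  blockers <- c(blockers, extra)
  for (bi in seq_along(blockers)) {
    tv <- tri_vertices(blockers[[bi]])
    soup[[bi]] <- tv
    own <- if (bi <= length(targets)) bi else NA_integer_
    owner <- c(owner, rep(own, nrow(blockers[[bi]]$faces)))
    face_of <- c(face_of, seq_len(nrow(blockers[[bi]]$faces)))
  }
  V1 <- do.call(rbind, lapply(soup, `[[`, "V1"))
  V2 <- do.call(rbind, lapply(soup, `[[`, "V2"))
  V3 <- do.call(rbind, lapply(soup, `[[`, "V3"))
  vn <- lapply(targets, vertex_normals)
  acc <- lapply(targets, function(t) numeric(nrow(t$vertices)))
  hits <- lapply(targets, function(t) numeric(nrow(t$vertices)))
  rng <- new_rng(seed)
  n_tri <- nrow(V1)
  E1 <- V2 - V1
  E2 <- V3 - V1
  for (g in seq_len(nrow(centers))) {
    if (P[g] == 0) next
    quantum <- P[g] / n_photons
    # isotropic directions
    z <- 2 * rng_unif(rng, n_photons) - 1
    phi <- 2 * pi * rng_unif(rng, n_photons)
    rxy <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(rxy * cos(phi), rxy * sin(phi), z)
    # first hit per ray: sweep triangles, Moller-Trumbore vectorized on rays
    best_t <- rep(Inf, n_photons)
    best_tri <- rep(NA_integer_, n_photons)
    orig <- centers[g, ]
    for (tri in seq_len(n_tri)) {
      e1 <- E1[tri, ]; e2 <- E2[tri, ]
      pvec <- cbind(dirs[, 2] * e2[3] - dirs[, 3] * e2[2],
                    dirs[, 3] * e2[1] - dirs[, 1] * e2[3],
                    dirs[, 1] * e2[2] - dirs[, 2] * e2[1])
      det <- pvec %*% e1
      tv <- orig - V1[tri, ]
      u <- (pvec %*% tv) / det
      qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
              tv[3] * e1[1] - tv[1] * e1[3],
              tv[1] * e1[2] - tv[2] * e1[1])
      v <- (dirs %*% qv) / det
      t <- sum(e2 * qv) / det
      ok <- abs(det) > 1e-12 & u >= 0 & v >= 0 & (u + v) <= 1 &
        t > 1e-9 & t < best_t
      ok <- as.vector(ok) & is.finite(t)
      if (any(ok)) {
        best_t[ok] <- t[ok]
        best_tri[ok] <- tri
      }
    }
    hit_rays <- which(!is.na(best_tri) & !is.na(owner[best_tri]))
    for (ph in hit_rays) {
      tg <- owner[best_tri[ph]]
      fidx <- face_of[best_tri[ph]]
      pt <- orig + best_t[ph] * dirs[ph, ]
      vs <- targets[[tg]]$faces[fidx, ]
      dv <- sweep(targets[[tg]]$vertices[vs, , drop = FALSE], 2, pt, "-")
      nearest <- vs[which.min(rowSums(dv^2))]
      acc[[tg]][nearest] <- acc[[tg]][nearest] + quantum
      hits[[tg]][nearest] <- hits[[tg]][nearest] + 1
    }
  }
  out <- vector("list", length(targets))
  for (tg in seq_along(targets)) {
    areas <- vn[[tg]]$areas
    if (any(areas <= 0)) stop("zero-area one-ring on mesh ", targets[[tg]]$id)
    quantum_density <- acc[[tg]] / areas
    se <- sqrt(pmax(hits[[tg]], 1)) * (acc[[tg]] / pmax(hits[[tg]], 1)) / areas
    out[[tg]] <- structure(
      list(values = quantum_density, mesh = targets[[tg]],
           mode = "montecarlo", occlusion = TRUE,
           n_photons = n_photons, seed = seed, se = se, hits = hits[[tg]]),
      class = "absorption_map")
  }
  out
}

#' @export
print.absorption_map <- function(x, ...) {
  cat("<absorption_map> mesh ", x$mesh$id, " (", x$mesh$class, "), ",
      length(x$values), " vertices, mode ", x$mode,
      if (x$mode == "montecarlo") paste0(", ", x$n_photons, " photons"),
      "\n", sep = "")
  invisible(x)
}

#' Aggregate an absorption map into object totals and top regions
#'
#' Area-weighted total absorbed power per object (`sum(value * vertex
#' area)`), and the `top_k` vertices by map value together with their
#' connected one-ring patches.
#'
#' @param maps a single `absorption_map` or list of them.
#' @param top_k number of top vertices to report per map.
#' @return list with `totals` (data.frame: object_id, class, total) and
#'   `top` (data.frame: object_id, vertex, value, patch_size).
#' @export
aggregate_absorption <- function(maps, top_k = 5) {
  if (inherits(maps, "absorption_map")) maps <- list(maps)
  totals <- data.frame(object_id = integer(0), class = character(0),
                       total = numeric(0))
  top <- data.frame(object_id = integer(0), vertex = integer(0),
                    value = numeric(0), patch_size = integer(0))
  for (mp in maps) {
    vn <- vertex_normals(mp$mesh)
    totals <- rbind(totals, data.frame(
      object_id = mp$mesh$id, class = mp$mesh$class,
      total = sum(mp$values * vn$areas)))
    k <- min(top_k, length(mp$values))
    ord <- order(mp$values, decreasing = TRUE)[seq_len(k)]
    # connected patch: vertices sharing a face with the top vertex and with
    # value above half the top value
    f <- mp$mesh$faces
    patch_size <- vapply(ord, function(vi) {
      ring <- unique(as.vector(f[rowSums(f == vi) > 0, ]))
      sum(mp$values[ring] >= mp$values[vi] / 2)
    }, integer(1))
    top <- rbind(top, data.frame(object_id = mp$mesh$id, vertex = ord,
                                 value = mp$values[ord],
                                 patch_size = patch_size))
  }
  list(totals = totals, top = top)
}
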