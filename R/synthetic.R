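# Synthetic fixtures: procedural neuropil scenes, planted glycogen granule
# distributions, Poisson synaptic event streams.  Everything is deterministic
# per seed (private RNG streams) so no external data is ever needed to
# exercise the analysis modules.

#' Scene recipe for a synthetic neuropil
#'
#' @param n_axons,n_dendrites number of tubes of each class.
#' @param n_boutons,n_spines number of spheres attached to axons / dendrites.
#' @param n_astro_blobs spheres composing the (multi-component) astrocyte.
#' @param box scene bounding box edge (um; cube at the origin corner).
#' @param subdiv icosphere subdivision for spheres (faces = 20*4^subdiv).
#' @param n_seg tube ring discretization.
#' @param seed RNG seed; same recipe + seed gives an identical scene.
#' @return list of class `scene_recipe`.
#' @export
scene_recipe <- function(n_axons = 4, n_dendrites = 2, n_boutons = 6,
                         n_spines = 4, n_astro_blobs = 3, box = 10,
                         subdiv = 1, n_seg = 8, seed = 1) {
  counts <- c(n_axons, n_dendrites, n_boutons, n_spines, n_astro_blobs)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (box <= 0) stop("box must be > 0")
  if (n_boutons > 0 && n_axons == 0) stop("boutons need at least one axon")
  if (n_spines > 0 && n_dendrites == 0) stop("spines need at least one dendrite")
  structure(list(n_axons = n_axons, n_dendrites = n_dendrites,
                 n_boutons = n_boutons, n_spines = n_spines,
                 n_astro_blobs = n_astro_blobs, box = box,
                 subdiv = subdiv, n_seg = n_seg, seed = seed),
            class = "scene_recipe")
}

#' Generate a synthetic neuropil scene
#'
#' Builds a miniature neuropil in a cubic box: axons and dendrites are capped
#' tubes crossing the box, boutons and spines are spheres centered on the
#' surface of a parent tube, and the astrocyte is a multi-component mesh of
#' disjoint spheres.  All meshes are watertight, outward-oriented and
#' labeled; object ids are assigned in generation order (axons, dendrites,
#' boutons, spines, astrocyte).  Deterministic per recipe seed.
#'
#' @param recipe a [scene_recipe()].
#' @return list with `meshes` (list of `surface_mesh`) and `manifest`
#'   (data.frame: id, class, n_vertices, n_faces).
#' @export
make_neuropil <- function(recipe) {
  stopifnot(inherits(recipe, "scene_recipe"))
  rng <- new_rng(recipe$seed)
  box <- recipe$box
  tube_r <- function(cls) if (cls == "axon") box / 40 else box / 25
  meshes <- list()
  id <- 0L
  centers_used <- matrix(numeric(0), 0, 4)  # x, y, z, clearance radius
  place_sphere <- function(r, attach = NULL) {
    # rejection-sample a center with clearance from previously placed spheres
    for (try in 1:200) {
      c0 <- if (is.null(attach)) rng_unif(rng, 3, r, box - r)
        else attach(try)
      if (!nrow(centers_used)) return(c0)
      dd <- sqrt(rowSums(sweep(centers_used[, 1:3, drop = FALSE], 2, c0, "-")^2))
      if (all(dd > centers_used[, 4] + r)) return(c0)
    }
    stop("box too small for the requested counts (sphere placement failed)")
  }
  tubes <- list()
  for (cls in c("axon", "dendrite")) {
    n <- if (cls == "axon") recipe$n_axons else recipe$n_dendrites
    for (i in seq_len(n)) {
      id <- id + 1L
      margin <- 2.5 * tube_r(cls)
      p0 <- rng_unif(rng, 3, margin, box - margin)
      dir <- rng_unif(rng, 3, -1, 1)
      dir <- dir / sqrt(sum(dir^2))
      len <- min(box / 2, 0.8 * box) * (0.5 + 0.5 * rng_unif(rng, 1))
      p1 <- p0 + dir * len
      p1 <- pmin(pmax(p1, margin), box - margin)
      if (sqrt(sum((p1 - p0)^2)) < box / 10) p1 <- p0 + c(box / 8, 0, 0)
      m <- tube_mesh(p0, p1, radius = tube_r(cls), n_seg = recipe$n_seg,
                     class = cls, id = id)
      meshes[[id]] <- m
      tubes[[length(tubes) + 1]] <- list(p0 = p0, p1 = p1, r = tube_r(cls),
                                         class = cls)
    }
  }
  attach_to_tube <- function(cls_parent, r_sphere) {
    parents <- Filter(function(t) t$class == cls_parent, tubes)
    function(try) {
      tb <- parents[[rng_int(rng, 1, length(parents))]]
      t <- rng_unif(rng, 1)
      ax <- tb$p1 - tb$p0
      # random direction perpendicular to the axis
      repeat {
        rd <- rng_unif(rng, 3, -1, 1)
        rd <- rd - sum(rd * ax) / sum(ax^2) * ax
        if (sum(rd^2) > 1e-6) break
      }
      rd <- rd / sqrt(sum(rd^2))
      c0 <- tb$p0 + t * ax + rd * (tb$r + 0.6 * r_sphere)
      pmin(pmax(c0, r_sphere), recipe$box - r_sphere)
    }
  }
  for (cls in c("bouton", "spine")) {
    n <- if (cls == "bouton") recipe$n_boutons else recipe$n_spines
    r <- if (cls == "bouton") box / 18 else box / 30
    parent <- if (cls == "bouton") "axon" else "dendrite"
    for (i in seq_len(n)) {
      id <- id + 1L
      c0 <- place_sphere(r, attach = attach_to_tube(parent, r))
      meshes[[id]] <- icosphere(c0, r, recipe$subdiv, class = cls, id = id)
      centers_used <- rbind(centers_used, c(c0, r))
    }
  }
  if (recipe$n_astro_blobs > 0) {
    id <- id + 1L
    r <- box / 12
    V <- matrix(numeric(0), 0, 3)
    F <- matrix(integer(0), 0, 3)
    for (b in seq_len(recipe$n_astro_blobs)) {
      c0 <- place_sphere(r * 1.05)
      centers_used <- rbind(centers_used, c(c0, r * 1.05))
      sp <- icosphere(c0, r, recipe$subdiv, class = "astrocyte", id = id)
      F <- rbind(F, sp$faces + nrow(V))
      V <- rbind(V, sp$vertices)
    }
    meshes[[id]] <- surface_mesh(V, F, class = "astrocyte", id = id)
  }
  manifest <- data.frame(
    id = vapply(meshes, `[[`, integer(1), "id"),
    class = vapply(meshes, `[[`, character(1), "class"),
    n_vertices = vapply(meshes, function(m) nrow(m$vertices), integer(1)),
    n_faces = vapply(meshes, function(m) nrow(m$faces), integer(1))
  )
  list(meshes = meshes, manifest = manifest)
}

#' Scatter glycogen granules with a planted nearest-class distribution
#'
#' With probability `p_bouton` a granule is placed strictly nearer a bouton
#' surface than any other mesh; otherwise strictly nearest a uniformly chosen
#' other class present in the scene.  Placement is rejection-sampled against
#' the exact nearest-neighbor assignment, so the planted truth table is
#' recoverable by [nearest_element_tally()] by construction.  Radii are drawn
#' uniformly from `r_range`.
#'
#' @param meshes scene mesh list (from [make_neuropil()]).
#' @param n number of granules (>= 1).
#' @param p_bouton polarization probability toward boutons, in `[0, 1]`.
#' @param seed RNG seed.
#' @param r_range granule radius range (um).
#' @param max_tries rejection budget per granule.
#' @return list with `granules` (data.frame x, y, z, r, host_id = 0) and
#'   `truth` (data.frame: granule, planted_class, planted_id).
#' @export
scatter_granules <- function(meshes, n, p_bouton = 0.75, seed = 1,
                             r_range = c(0.01, 0.04), max_tries = 400) {
  if (n < 1) stop("n must be >= 1")
  if (p_bouton < 0 || p_bouton > 1) stop("p_bouton must be in [0, 1]")
  classes <- vapply(meshes, `[[`, character(1), "class")
  ids <- vapply(meshes, `[[`, integer(1), "id")
  if (!any(classes == "bouton")) stop("scene has no boutons")
  other <- setdiff(unique(classes), "bouton")
  rng <- new_rng(seed)
  bbox <- do.call(rbind, lapply(meshes, function(m) mesh_bbox(m)))
  lo <- apply(bbox, 2, min); hi <- apply(bbox, 2, max)
  out <- matrix(NA_real_, n, 4)
  truth <- data.frame(granule = seq_len(n),
                      planted_class = character(n),
                      planted_id = integer(n), stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    want_bouton <- rng_unif(rng, 1) < p_bouton
    want_class <- if (want_bouton) "bouton"
      else other[rng_int(rng, 1, length(other))]
    cand_meshes <- which(classes == want_class)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      mi <- cand_meshes[rng_int(rng, 1, length(cand_meshes))]
      m <- meshes[[mi]]
      # sample a point just outside a random face of the wanted mesh
      fi <- rng_int(rng, 1, nrow(m$faces))
      w <- rng_unif(rng, 3)
      w <- w / sum(w)
      tv <- m$vertices[m$faces[fi, ], , drop = FALSE]
      base <- colSums(tv * w)
      nrm <- face_normals(m)[fi, ]
      off <- rng_unif(rng, 1, 0.02, 0.12)
      pos <- base + nrm * off
      # verify the strict nearest-mesh condition exactly
      dd <- vapply(meshes, function(mm)
        dist_points_mesh(matrix(pos, 1), mm)$dist, numeric(1))
      if (which.min(dd) == mi && sum(abs(dd - min(dd)) < 1e-12) == 1) {
        out[g, ] <- c(pos, rng_unif(rng, 1, r_range[1], r_range[2]))
        truth$planted_class[g] <- want_class
        truth$planted_id[g] <- ids[mi]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("rejection budget exhausted while placing granule ", g,
           " near class ", want_class)
  }
  granules <- data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
                         r = out[, 4], host_id = 0L)
  list(granules = granules, truth = truth)
}

#' Poisson synaptic event stream on a voxel grid
#'
#' Homogeneous Poisson events per voxel at the given rates, with positions
#' uniform within the generating voxel and identical quanta `q`; sorted by
#' time.  Deterministic per seed.
#'
#' @param grid a [voxel_grid()].
#' @param rate_field per-voxel event rates (Hz); scalar or one per voxel
#'   (linear order, x fastest).
#' @param q quanta per event (mM um^3 glutamate equivalent, > 0).
#' @param t_span length-2 time span (s).
#' @param seed RNG seed.
#' @return events data.frame (`t`, `x`, `y`, `z`, `q`) sorted by `t`.
#' @export
make_event_stream <- function(grid, rate_field, q = 50, t_span = c(0, 1),
                              seed = 1) {
  nv <- n_voxels(grid)
  rate <- rep_len(rate_field, nv)
  if (any(rate < 0)) stop("rates must be >= 0")
  if (q <= 0) stop("q must be > 0")
  rng <- new_rng(seed)
  span <- t_span[2] - t_span[1]
  counts <- rng_pois(rng, nv, rate * span)
  total <- sum(counts)
  if (total == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), q = numeric(0)))
  vox <- rep(seq_len(nv), counts)
  vx <- (vox - 1L) %% grid$dims[1]
  vy <- ((vox - 1L) %/% grid$dims[1]) %% grid$dims[2]
  vz <- (vox - 1L) %/% (grid$dims[1] * grid$dims[2])
  u <- matrix(rng_unif(rng, 3 * total), total, 3)
  # strictly inside the half-open cell so voxel assignment is unambiguous
  u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
  ev <- data.frame(
    t = t_span[1] + rng_unif(rng, total) * span,
    x = grid$origin[1] + (vx + u[, 1]) * grid$h,
    y = grid$origin[2] + (vy + u[, 2]) * grid$h,
    z = grid$origin[3] + (vz + u[, 3]) * grid$h,
    q = q
  )
  ev[order(ev$t), , drop = FALSE]
}
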