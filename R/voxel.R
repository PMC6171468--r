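# Voxelized simulation: synaptic release events are binned onto a cubic
# grid, each voxel runs an independent metabolic unit (no inter-voxel
# exchange by default; an optional explicit-Euler ECS diffusion pass can be
# enabled for exploration), and per-voxel species time series are collected.

#' Cubic voxel grid
#'
#' @param origin numeric triple, world position of the grid corner (um).
#' @param h voxel edge length (um); the default mirrors the 50 um tiling of
#'   the large-scale simulation this module emulates.
#' @param dims integer triple, voxel counts per axis.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin = c(0, 0, 0), h = 50, dims = c(1, 1, 1)) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (h <= 0) stop("voxel edge h must be > 0")
  dims <- as.integer(dims)
  if (any(dims < 1)) stop("dims must be >= 1")
  structure(list(origin = as.numeric(origin), h = h, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = "x"), " voxels, h = ",
      x$h, " um, origin (", paste(x$origin, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

# 1-based linear index from 0-based (i,j,k) triple, x fastest
voxel_linear <- function(grid, ijk) {
  ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3]) + 1L
}

#' Map event positions to voxel indices
#'
#' Half-open cells: voxel index (0-based) per axis is
#' `floor((pos - origin)/h)`, with a position on an internal boundary
#' belonging to the higher cell.  Positions outside the grid extent are an
#' error (no clamping).
#'
#' @param grid a [voxel_grid()].
#' @param pos n x 3 matrix of positions (um).
#' @return n x 3 integer matrix of 0-based voxel indices, plus attribute
#'   `linear` (1-based linear index, x fastest).
#' @export
voxel_index <- function(grid, pos) {
  pos <- matrix(pos, ncol = 3)
  rel <- sweep(pos, 2, grid$origin, "-") / grid$h
  ijk <- floor(rel)
  hi <- sweep(ijk, 2, as.numeric(grid$dims), ">=")
  lo <- ijk < 0
  if (any(hi) || any(lo)) {
    bad <- which(apply(hi | lo, 1, any))
    stop("event position(s) outside grid extent at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  ijk <- matrix(as.integer(ijk), ncol = 3)
  attr(ijk, "linear") <- voxel_linear(grid, ijk)
  ijk
}

#' Bin release events into per-voxel release-rate series
#'
#' Each event of `q` quanta (mM um^3 of glutamate equivalent) contributes
#' `q/(dt_bin * h^3)` mM/s to its voxel's release-rate bin, so total quanta
#' are conserved exactly across the binning:
#' `sum(rate) * dt_bin * h^3 == sum(q)`.
#'
#' @param events data.frame with columns `t` (s, non-decreasing), `x`, `y`,
#'   `z` (um), `q` (> 0).
#' @param grid a [voxel_grid()].
#' @param dt_bin bin width (s).
#' @param t_span length-2 span covered by the bins; defaults to
#'   `c(0, max(t))` rounded up to a whole bin.
#' @return object of class `voxel_drive`: list with `rate` (matrix, one row
#'   per bin, one column per voxel, mM/s), `t_edges`, `grid`, `dt_bin`.
#' @export
assign_events <- function(events, grid, dt_bin = 0.01, t_span = NULL) {
  validate_events(events)
  if (is.null(t_span)) {
    t_hi <- if (nrow(events)) ceiling(max(events$t) / dt_bin + 1e-12) * dt_bin
            else dt_bin
    t_span <- c(0, max(t_hi, dt_bin))
  }
  n_bins <- max(1L, as.integer(ceiling((t_span[2] - t_span[1]) / dt_bin - 1e-9)))
  nv <- n_voxels(grid)
  rate <- matrix(0, n_bins, nv)
  if (nrow(events)) {
    if (any(events$t < t_span[1]) || any(events$t > t_span[2]))
      stop("event time(s) outside t_span")
    ijk <- voxel_index(grid, cbind(events$x, events$y, events$z))
    vox <- attr(ijk, "linear")
    bin <- pmin(n_bins, floor((events$t - t_span[1]) / dt_bin) + 1L)
    add <- events$q / (dt_bin * grid$h^3)
    for (r in seq_along(vox))
      rate[bin[r], vox[r]] <- rate[bin[r], vox[r]] + add[r]
  }
  structure(list(rate = rate, t_edges = t_span[1] + dt_bin * 0:n_bins,
                 grid = grid, dt_bin = dt_bin),
            class = "voxel_drive")
}

# piecewise-constant lookup into one voxel's binned rate series
voxel_rate_fun <- function(vdrive, v, basal) {
  rate <- vdrive$rate[, v]
  t0 <- vdrive$t_edges[1]
  dt <- vdrive$dt_bin
  nb <- length(rate)
  function(t) {
    i <- floor((t - t0) / dt) + 1
    i[i < 1 | i > nb] <- NA
    out <- rate[i]
    out[is.na(out)] <- 0
    out + basal
  }
}

#' Simulate a metabolic unit in every voxel
#'
#' Runs one independent NGV unit per voxel (no inter-voxel exchange), driven
#' by that voxel's binned glutamate release on top of the basal release.
#' Snapshots of the requested species are collected every `dt_snap` seconds;
#' results are independent of voxel iteration order by construction (each
#' voxel's integration depends only on its own drive).
#'
#' @param grid a [voxel_grid()].
#' @param vdrive a `voxel_drive` from [assign_events()], or `NULL` for a
#'   resting grid.
#' @param params model parameters.
#' @param t_span length-2 integration span (s).
#' @param dt_snap snapshot interval (s); default 0.010, matching the 10 ms
#'   release cadence of the emulated large-scale run.
#' @param species species to record (default `"ATP_n"`).
#' @param state0 initial state; defaults to [resting_state()] of `params`.
#' @param diffusion optional list enabling the exploratory explicit-Euler
#'   ECS diffusion pass, e.g. `list(D = c(GLU_e = 5), dt = 0.01)` with D in
#'   um^2/s; `NULL` (default) = no exchange.
#' @param ... further arguments to [integrate_unit()].
#' @return object of class `volumetric_series`: list with `times`, `values`
#'   (list per species of snapshot x voxel matrices), `grid`, `species`,
#'   `normalization` ("none"), `resting` (named resting values).
#' @export
simulate_grid <- function(grid, vdrive, params, t_span, dt_snap = 0.010,
                          species = "ATP_n", state0 = NULL, diffusion = NULL,
                          ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  unknown <- setdiff(species, NGV_SPECIES)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (!is.null(vdrive) && !identical(vdrive$grid$dims, grid$dims))
    stop("voxel drive was binned on a different grid")
  if (!is.null(vdrive) && vdrive$t_edges[length(vdrive$t_edges)] < t_span[2] - 1e-12)
    stop("voxel drive does not cover t_span for every voxel")
  if (is.null(state0)) state0 <- resting_state(params)
  nv <- n_voxels(grid)
  if (!is.null(diffusion))
    return(simulate_grid_diffusive(grid, vdrive, params, t_span, dt_snap,
                                   species, state0, diffusion))
  n_out <- floor((t_span[2] - t_span[1]) / dt_snap + 1e-9) + 1L
  values <- lapply(species, function(s) matrix(NA_real_, n_out, nv))
  names(values) <- species
  times <- NULL
  for (v in seq_len(nv)) {
    drv <- voxel_drive_for(vdrive, v, params, t_span)
    traj <- tryCatch(
      integrate_unit(state0, params, drv, t_span, dt_out = dt_snap, ...),
      error = function(e) stop("voxel ", v, ": ", conditionMessage(e)))
    times <- traj$times
    for (s in species) values[[s]][, v] <- traj$states[, s]
  }
  structure(list(times = times, values = values, grid = grid,
                 species = species, normalization = "none",
                 resting = unclass(state0)[species]),
            class = "volumetric_series")
}

voxel_drive_for <- function(vdrive, v, params, t_span) {
  if (is.null(vdrive))
    return(resting_drive(params, t_max = t_span[2]))
  ngv_drive(t_max = max(t_span[2], vdrive$t_edges[length(vdrive$t_edges)]),
            basal = list(j_rel = params$j_rel_rest),
            j_rel_fun = voxel_rate_fun(vdrive, v, params$j_rel_rest))
}

# Exploratory mode: operator-split explicit Euler exchange of ECS species
# between face-adjacent voxels after each snapshot interval.
simulate_grid_diffusive <- function(grid, vdrive, params, t_span, dt_snap,
                                    species, state0, diffusion) {
  D <- diffusion$D
  if (is.null(names(D)) || !all(names(D) %in% c("GLU_e", "GLC_e", "LAC_e")))
    stop("diffusion$D must be named with ECS species (GLU_e, GLC_e, LAC_e)")
  nv <- n_voxels(grid)
  n_out <- floor((t_span[2] - t_span[1]) / dt_snap + 1e-9) + 1L
  states <- matrix(rep(unclass(state0), each = nv), nrow = nv,
                   dimnames = list(NULL, NGV_SPECIES))
  values <- lapply(species, function(s) matrix(NA_real_, n_out, nv))
  names(values) <- species
  for (s in species) values[[s]][1, ] <- states[, s]
  times <- t_span[1] + (seq_len(n_out) - 1L) * dt_snap
  lam_max <- max(D) * dt_snap / grid$h^2
  if (lam_max > 1 / 6)
    stop("diffusion step unstable: D*dt/h^2 = ", round(lam_max, 4), " > 1/6")
  for (i in 2:n_out) {
    for (v in seq_len(nv)) {
      drv <- voxel_drive_for(vdrive, v, params, t_span)
      traj <- integrate_unit(ngv_state(states[v, ], params), params, drv,
                             c(times[i - 1], times[i]), dt_out = dt_snap)
      states[v, ] <- traj$states[nrow(traj$states), ]
    }
    for (sp in names(D)) {
      lam <- D[[sp]] * dt_snap / grid$h^2
      states[, sp] <- states[, sp] + lam * laplacian3d(states[, sp], grid$dims)
    }
    for (s in species) values[[s]][i, ] <- states[, s]
  }
  structure(list(times = times, values = values, grid = grid,
                 species = species, normalization = "none",
                 resting = unclass(state0)[species]),
            class = "volumetric_series")
}

# discrete 6-neighbour Laplacian on the flattened grid (zero-flux borders)
laplacian3d <- function(x, dims) {
  a <- array(x, dim = dims)
  out <- array(0, dim = dims)
  pad <- function(a, shift, axis) {
    idx <- lapply(dims, seq_len)
    src <- idx
    src[[axis]] <- pmin(pmax(idx[[axis]] + shift, 1L), dims[axis])
    do.call(`[`, c(list(a), src))
  }
  for (axis in 1:3) {
    out <- out + pad(a, 1L, axis) + pad(a, -1L, axis) - 2 * a
  }
  as.vector(out)
}

#' @export
print.volumetric_series <- function(x, ...) {
  cat("<volumetric_series> ", length(x$times), " snapshots x ",
      n_voxels(x$grid), " voxels; species: ",
      paste(x$species, collapse = ", "), "; normalization: ",
      x$normalization, "\n", sep = "")
  invisible(x)
}

#' Normalize a volumetric series
#'
#' `"fold"` (default) divides every value by the species' resting value,
#' matching the normalized-ATP rendering convention of volumetric metabolite
#' movies; `"minmax"` rescales each species to `[0, 1]` over the whole run;
#' `"none"` undoes a fold normalization.
#'
#' @param series a `volumetric_series`.
#' @param mode "fold", "minmax" or "none".
#' @return a new `volumetric_series` with `normalization` recorded.
#' @export
normalize_field <- function(series, mode = c("fold", "minmax", "none")) {
  mode <- match.arg(mode)
  out <- series
  if (mode == "fold") {
    if (series$normalization != "none")
      stop("can only fold-normalize an unnormalized series")
    for (s in series$species) {
      ref <- series$resting[[s]]
      if (!is.finite(ref) || ref == 0)
        stop("resting value of ", s, " is zero; cannot fold-normalize")
      out$values[[s]] <- series$values[[s]] / ref
    }
  } else if (mode == "minmax") {
    if (series$normalization != "none")
      stop("can only minmax-normalize an unnormalized series")
    for (s in series$species) {
      v <- series$values[[s]]
      rng <- range(v)
      out$values[[s]] <- if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
      attr(out$values[[s]], "range") <- rng
    }
  } else {
    if (series$normalization != "fold")
      stop("can only denormalize a fold-normalized series")
    for (s in series$species)
      out$values[[s]] <- series$values[[s]] * series$resting[[s]]
  }
  out$normalization <- mode
  out
}
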