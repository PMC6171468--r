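# Adaptive explicit Runge-Kutta integration of one metabolic unit.
#
# No general-purpose ODE solver is available in the supported stack, so the
# integrator is authored here: Dormand-Prince 5(4) with standard embedded
# error control.  Steps land exactly on the output grid (no interpolation),
# which makes trajectories bit-reproducible and voxel runs schedule
# independent.  The model's parameterization keeps its fastest time constants
# at the millisecond scale, well within reach of an explicit method at the
# default tolerances; see the methods vignette for the stiffness discussion.

# Dormand-Prince 5(4) tableau
DP_C <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
DP_A <- list(
  c2 = c(1/5),
  c3 = c(3/40, 9/40),
  c4 = c(44/45, -56/15, 32/9),
  c5 = c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c6 = c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c7 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
)
DP_B5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
DP_B4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

dp45_step <- function(rhs, t, y, h, k1) {
  k2 <- rhs(t + DP_C[2] * h, y + h * DP_A$c2[1] * k1)
  k3 <- rhs(t + DP_C[3] * h, y + h * (DP_A$c3[1] * k1 + DP_A$c3[2] * k2))
  k4 <- rhs(t + DP_C[4] * h,
            y + h * (DP_A$c4[1] * k1 + DP_A$c4[2] * k2 + DP_A$c4[3] * k3))
  k5 <- rhs(t + DP_C[5] * h,
            y + h * (DP_A$c5[1] * k1 + DP_A$c5[2] * k2 + DP_A$c5[3] * k3 +
                     DP_A$c5[4] * k4))
  k6 <- rhs(t + h,
            y + h * (DP_A$c6[1] * k1 + DP_A$c6[2] * k2 + DP_A$c6[3] * k3 +
                     DP_A$c6[4] * k4 + DP_A$c6[5] * k5))
  y5 <- y + h * (DP_B5[1] * k1 + DP_B5[3] * k3 + DP_B5[4] * k4 +
                 DP_B5[5] * k5 + DP_B5[6] * k6)
  k7 <- rhs(t + h, y5)  # FSAL
  err <- h * ((DP_B5[1] - DP_B4[1]) * k1 + (DP_B5[3] - DP_B4[3]) * k3 +
              (DP_B5[4] - DP_B4[4]) * k4 + (DP_B5[5] - DP_B4[5]) * k5 +
              (DP_B5[6] - DP_B4[6]) * k6 - DP_B4[7] * k7)
  list(y = y5, err = err, k_last = k7)
}

#' Integrate one metabolic unit over time
#'
#' Adaptive Dormand-Prince 5(4) integration of the NGV unit under an external
#' drive, sampled on a regular output grid.  State invariants are enforced at
#' every output point; a concentration dipping below `-atol` raises an error
#' rather than being clamped.
#'
#' @param state0 initial state (see [ngv_state()], [resting_state()]).
#' @param params model parameters.
#' @param drive an [ngv_drive()] covering `t_span`.
#' @param t_span length-2 numeric, integration span in seconds.
#' @param dt_out output sampling interval (s).
#' @param rtol,atol relative/absolute local error tolerances.
#' @param max_step largest internal step (s); also caps how far the
#'   integrator can skip over short drive pulses.
#' @return object of class `ngv_trajectory`: list with `times`, `states`
#'   (matrix, one row per output time), `fluxes` (matrix of
#'   [compute_fluxes()] outputs at output times), `params`, `drive`, and
#'   `metadata` (tolerances, step statistics, mechanism switches).
#' @export
integrate_unit <- function(state0, params, drive, t_span, dt_out = 0.01,
                           rtol = 1e-6, atol = 1e-9, max_step = 0.05) {
  validate_params(params)
  y <- unclass(state0)[NGV_SPECIES]
  validate_state(y, params)
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], dt_out > 0)
  if (!inherits(drive, "ngv_drive")) stop("drive must be an ngv_drive")
  if (drive$t_max < t_span[2] - 1e-12)
    stop("drive span [0, ", drive$t_max, "] does not cover t_span end ",
         t_span[2])

  rhs <- ngv_rhs_factory(params, drive)
  n_out <- floor((t_span[2] - t_span[1]) / dt_out + 1e-9) + 1L
  times <- t_span[1] + (seq_len(n_out) - 1L) * dt_out
  states <- matrix(NA_real_, n_out, length(NGV_SPECIES),
                   dimnames = list(NULL, NGV_SPECIES))
  states[1L, ] <- y

  t <- t_span[1]
  k1 <- rhs(t, y)
  h <- min(max_step, dt_out / 4)
  n_steps <- 0L
  n_rejected <- 0L
  safety <- 0.9

  for (i in 2L:n_out) {
    t_target <- times[i]
    while (t < t_target - 1e-12) {
      h <- min(h, max_step, t_target - t)
      st <- dp45_step(rhs, t, y, h, k1)
      sc <- atol + rtol * pmax(abs(y), abs(st$y))
      err_norm <- max(abs(st$err / sc))
      if (is.finite(err_norm) && err_norm <= 1) {
        t <- t + h
        y <- st$y
        k1 <- st$k_last
        n_steps <- n_steps + 1L
        fac <- safety * err_norm^-0.2
        h <- h * min(5, max(0.2, fac))
      } else {
        n_rejected <- n_rejected + 1L
        if (!is.finite(err_norm)) {
          h <- h / 10
        } else {
          h <- h * max(0.1, safety * err_norm^-0.2)
        }
        if (h < 1e-12)
          stop("integrator failure: step size underflow at t = ",
               format(t, digits = 10), " s")
      }
    }
    if (any(y < -atol)) {
      bad <- NGV_SPECIES[y < -atol]
      stop("negative concentration beyond -atol at t = ",
           format(t, digits = 10), " s in: ", paste(bad, collapse = ", "))
    }
    y[y < 0 & y > -atol] <- 0  # round-off snap within the stated tolerance
    validate_state(y, params, tol = 10 * atol)
    states[i, ] <- y
  }

  fx <- t(vapply(seq_len(n_out), function(i)
    unlist(compute_fluxes(states[i, ], params, drive_at(drive, times[i]),
                          validate = FALSE)),
    numeric(33)))
  structure(list(
    times = times, states = states, fluxes = fx,
    params = params, drive = drive,
    metadata = list(rtol = rtol, atol = atol, dt_out = dt_out,
                    n_steps = n_steps, n_rejected = n_rejected,
                    transport_off = isTRUE(params$transport_off),
                    mito_off = isTRUE(params$mito_off))
  ), class = "ngv_trajectory")
}

#' @export
print.ngv_trajectory <- function(x, ...) {
  cat("<ngv_trajectory> ", length(x$times), " samples over [",
      x$times[1], ", ", x$times[length(x$times)], "] s (",
      x$metadata$n_steps, " accepted steps)\n", sep = "")
  invisible(x)
}

#' Write a trajectory as long-format CSV plus JSON metadata
#'
#' One row per (time, species) pair with the compartment split out of the
#' species suffix; a JSON sidecar (`<path>.meta.json`) records tolerances,
#' switches and the parameter hash.
#'
#' @param traj an `ngv_trajectory`.
#' @param path CSV output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  comp_of <- function(sp) {
    suf <- sub("^.*_", "", sp)
    c(n = "neuron", a = "astrocyte", e = "ecs", c = "capillary")[[suf]]
  }
  n_t <- length(traj$times)
  sp <- colnames(traj$states)
  df <- data.frame(
    t = rep(traj$times, times = length(sp)),
    compartment = rep(vapply(sp, comp_of, character(1)), each = n_t),
    species = rep(sp, each = n_t),
    value = as.vector(traj$states)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(traj$metadata, list(params_hash = params_hash(traj$params)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Stable content hash of a parameter list (md5 of its canonical JSON).
params_hash <- function(params) {
  js <- jsonlite::toJSON(unclass(params)[order(names(params))],
                         auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(js, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
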