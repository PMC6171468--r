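# External drive of the metabolic unit: glutamate release, cerebral blood
# flow, noradrenaline and (optionally) injected current forwarded to the
# Hodgkin-Huxley module.  A drive is a set of piecewise segment tables
# compiled into fast lookup functions; segments serialize losslessly to the
# TOML-subset config format.

DRIVE_SERIES <- c("j_rel", "cbf", "ne", "i_ext")

compile_series <- function(segments, basal) {
  if (is.null(segments) || nrow(segments) == 0)
    return(function(t) rep(basal, length(t)))
  s <- segments[order(segments$t0), , drop = FALSE]
  t0 <- s$t0; t1 <- s$t1; val <- s$value
  function(t) {
    out <- rep(basal, length(t))
    for (i in seq_along(t0)) {
      hit <- t >= t0[i] & t < t1[i]
      out[hit] <- val[i]
    }
    out
  }
}

#' Construct an external drive
#'
#' A drive holds four non-negative time series over `[0, t_max]`: glutamate
#' release flux into the ECS `j_rel` (mM/s), cerebral blood flow `cbf`
#' (dimensionless multiple of the baseline exchange rate `F_0`),
#' noradrenaline `ne` (uM) and injected current `i_ext` (uA/cm2, forwarded to
#' the activity module when Hodgkin-Huxley coupling is on).  Each series is a
#' basal constant overlaid with piecewise-constant pulse segments
#' (`data.frame(t0, t1, value)`, half-open `[t0, t1)`).
#'
#' @param t_max span end (s).
#' @param basal named list of basal constants (defaults: `j_rel` 1e-4,
#'   `cbf` 1, `ne` 0, `i_ext` 0).
#' @param segments named list of segment data frames, keyed by series name.
#' @param j_rel_fun optional function(t) overriding the `j_rel` series
#'   entirely (used for spike-train-derived release); must be non-negative
#'   on the span.
#' @return object of class `ngv_drive` with callable elements `$j_rel`,
#'   `$cbf`, `$ne`, `$i_ext`.
#' @export
ngv_drive <- function(t_max, basal = list(), segments = list(),
                      j_rel_fun = NULL) {
  stopifnot(is.numeric(t_max), t_max > 0)
  base <- list(j_rel = 1e-4, cbf = 1, ne = 0, i_ext = 0)
  base[names(basal)] <- basal
  bad <- vapply(base, function(v) !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("basal drive values must be finite and non-negative: ",
         paste(names(base)[bad], collapse = ", "))
  segs <- list()
  for (nm in names(segments)) {
    if (!nm %in% DRIVE_SERIES) stop("unknown drive series: ", nm)
    s <- segments[[nm]]
    stopifnot(is.data.frame(s), all(c("t0", "t1", "value") %in% names(s)))
    if (any(s$value < 0)) stop("drive series must be non-negative: ", nm)
    if (any(s$t1 <= s$t0)) stop("drive segment with t1 <= t0 in series ", nm)
    if (any(s$t0 < 0) || any(s$t1 > t_max))
      stop("drive segment outside [0, t_max] in series ", nm)
    s <- s[order(s$t0), , drop = FALSE]
    if (nrow(s) > 1 && any(s$t0[-1] < s$t1[-nrow(s)]))
      stop("overlapping contradictory segments in series ", nm)
    segs[[nm]] <- s
  }
  fns <- lapply(DRIVE_SERIES, function(nm)
    compile_series(segs[[nm]], base[[nm]]))
  names(fns) <- DRIVE_SERIES
  if (!is.null(j_rel_fun)) fns$j_rel <- j_rel_fun
  structure(c(fns, list(t_max = t_max, basal = base, segments = segs,
                        custom_j_rel = !is.null(j_rel_fun))),
            class = "ngv_drive")
}

#' @export
print.ngv_drive <- function(x, ...) {
  cat("<ngv_drive> span [0, ", x$t_max, "] s; basal: ",
      paste(names(x$basal), unlist(x$basal), sep = "=", collapse = ", "),
      "\n", sep = "")
  for (nm in names(x$segments))
    cat("  ", nm, ": ", nrow(x$segments[[nm]]), " segment(s)\n", sep = "")
  if (isTRUE(x$custom_j_rel)) cat("  j_rel: custom function\n")
  invisible(x)
}

#' Named drive protocols
#'
#' Library of stock protocols for the metabolic unit:
#' \describe{
#'   \item{"rest"}{all series at basal constants.}
#'   \item{"stimulus"}{a single glutamate release pulse (default 0.5 mM/s
#'     for 2 s starting at t = 1 s), emulating a burst of synaptic activity.}
#'   \item{"ne_pulse"}{a noradrenaline pulse (default 0.5 uM for 10 s at
#'     t = 1 s) on top of basal release.}
#'   \item{"cbf_step"}{a step increase of cerebral blood flow (default to
#'     1.5x baseline from t = 1 s to span end).}
#' }
#'
#' @param name protocol name.
#' @param t_max span (s); default 10.
#' @param magnitude pulse magnitude (protocol units; see above).
#' @param t_on,duration pulse timing (s).
#' @param j_rel_rest basal glutamate release (mM/s).
#' @return an [ngv_drive()] object.
#' @export
make_drive_profile <- function(name = c("rest", "stimulus", "ne_pulse", "cbf_step"),
                               t_max = 10, magnitude = NULL, t_on = 1,
                               duration = NULL, j_rel_rest = 1e-4) {
  name <- match.arg(name)
  basal <- list(j_rel = j_rel_rest)
  seg <- function(value, dur) {
    if (t_on < 0 || t_on > t_max) stop("t_on outside [0, t_max]")
    if (t_on + dur > t_max) stop("pulse extends beyond t_max")
    data.frame(t0 = t_on, t1 = t_on + dur, value = value)
  }
  segments <- switch(name,
    rest = list(),
    stimulus = list(j_rel = seg(magnitude %||% 0.5, duration %||% 2)),
    ne_pulse = list(ne = seg(magnitude %||% 0.5, duration %||% 10)),
    cbf_step = list(cbf = seg(magnitude %||% 1.5, duration %||% (t_max - t_on)))
  )
  d <- ngv_drive(t_max, basal = basal, segments = segments)
  d$protocol <- name
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize a drive to the TOML-subset config format
#'
#' Segment-based drives round-trip exactly; drives built from a custom
#' `j_rel` function are rejected (serialize the generating spike train
#' instead).
#'
#' @param drive an `ngv_drive`.
#' @param path file path.
#' @return `read_drive_toml()` returns an `ngv_drive`.
#' @export
write_drive_toml <- function(drive, path) {
  if (isTRUE(drive$custom_j_rel))
    stop("cannot serialize a drive with a custom j_rel function")
  x <- list(t_max = drive$t_max, basal = drive$basal)
  for (nm in names(drive$segments)) {
    s <- drive$segments[[nm]]
    x[[paste0("segments_", nm)]] <-
      list(t0 = s$t0, t1 = s$t1, value = s$value)
  }
  write_toml(x, path)
}

#' @rdname write_drive_toml
#' @export
read_drive_toml <- function(path) {
  kv <- read_toml(path)
  if (is.null(kv$t_max)) stop(path, ": drive config lacks t_max")
  segments <- list()
  for (nm in DRIVE_SERIES) {
    tab <- kv[[paste0("segments_", nm)]]
    if (!is.null(tab))
      segments[[nm]] <- data.frame(t0 = tab$t0, t1 = tab$t1, value = tab$value)
  }
  ngv_drive(kv$t_max, basal = kv$basal %||% list(), segments = segments)
}

# Drive sample at a single time point (list form used by compute_fluxes).
drive_at <- function(drive, t) {
  list(j_rel = drive$j_rel(t), cbf = drive$cbf(t), ne = drive$ne(t))
}

#' Resting drive for a parameter set
#'
#' Constant basal drive (`j_rel = j_rel_rest`, `cbf = 1`, `ne = 0`) used by
#' [resting_state()] and as the reference for normalization.
#'
#' @param params model parameters.
#' @param t_max span (s).
#' @return an `ngv_drive`.
#' @export
resting_drive <- function(params = ngv_default_params(), t_max = 100) {
  make_drive_profile("rest", t_max = t_max, j_rel_rest = params$j_rel_rest)
}
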