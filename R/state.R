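# State vector of one NGV metabolic unit.
#
# The state is a plain named numeric vector (fast to integrate); the helpers
# here construct, validate and derive from it.  Conserved counterparts (ADP,
# NAD+, Cr) are derived on demand and never stored, so the adenine, NAD and
# creatine pools cannot drift by construction.

NGV_SPECIES <- c(
  "Na_n", "GLC_n", "G6P_n", "PYR_n", "LAC_n", "NADHc_n", "NADHm_n",
  "ATP_n", "PCr_n", "O2_n",
  "Na_a", "GLC_a", "G6P_a", "PYR_a", "LAC_a", "NADHc_a", "NADHm_a",
  "ATP_a", "PCr_a", "O2_a",
  "GLY_a", "cAMP_a",
  "GLU_e", "GLC_e", "LAC_e",
  "GLC_c", "LAC_c", "O2_c"
)

#' Species of the NGV state vector
#'
#' Names and order of the stored state variables.  Suffixes: `_n` neuron,
#' `_a` astrocyte, `_e` extracellular space, `_c` capillary.  All are mM
#' except `cAMP_a` (uM).  `GLY_a` counts glucosyl units.
#'
#' @return character vector of species names.
#' @export
ngv_species <- function() NGV_SPECIES

#' Construct and validate an NGV state vector
#'
#' @param x named numeric vector covering every species in [ngv_species()]
#'   (order-free; reordered internally).
#' @param params parameters, used to check pool caps.
#' @return named numeric vector of class `ngv_state`.
#' @export
ngv_state <- function(x, params = ngv_default_params()) {
  if (is.null(names(x))) stop("state must be a named vector")
  missing <- setdiff(NGV_SPECIES, names(x))
  if (length(missing))
    stop("state is missing species: ", paste(missing, collapse = ", "))
  y <- x[NGV_SPECIES]
  validate_state(y, params)
  structure(y, class = "ngv_state")
}

#' Validate NGV state invariants
#'
#' All stored fields must be finite and non-negative; ATP, cytosolic and
#' mitochondrial NADH and PCr must not exceed their pool totals.
#'
#' @param y named numeric state vector.
#' @param params parameters providing pool totals.
#' @param tol slack for the non-negativity / cap checks (integration
#'   round-off); default 0.
#' @return `y` invisibly, or an error naming the offending field.
#' @export
validate_state <- function(y, params, tol = 0) {
  if (any(!is.finite(y))) {
    bad <- names(y)[!is.finite(y)]
    stop("non-finite state field(s): ", paste(bad, collapse = ", "))
  }
  if (any(y < -tol)) {
    bad <- names(y)[y < -tol]
    stop("negative concentration in field(s): ", paste(bad, collapse = ", "))
  }
  caps <- c(ATP_n = params$A_tot, ATP_a = params$A_tot,
            NADHc_n = params$Nc_tot, NADHc_a = params$Nc_tot,
            NADHm_n = params$Nm_tot, NADHm_a = params$Nm_tot,
            PCr_n = params$C_tot, PCr_a = params$C_tot)
  over <- names(caps)[y[names(caps)] > caps + tol]
  if (length(over))
    stop("pool cap exceeded in field(s): ", paste(over, collapse = ", "))
  invisible(y)
}

#' Derived (conserved-counterpart) quantities of a state
#'
#' ADP = A_tot - ATP, NAD+ (cytosolic/mitochondrial) = pool - NADH,
#' Cr = C_tot - PCr, per cell type.
#'
#' @param y state vector.
#' @param params parameters providing pool totals.
#' @return named numeric vector `ADP_n`, `ADP_a`, `NADc_n`, `NADc_a`,
#'   `NADm_n`, `NADm_a`, `Cr_n`, `Cr_a`.
#' @export
ngv_derived <- function(y, params) {
  c(ADP_n = params$A_tot - y[["ATP_n"]],
    ADP_a = params$A_tot - y[["ATP_a"]],
    NADc_n = params$Nc_tot - y[["NADHc_n"]],
    NADc_a = params$Nc_tot - y[["NADHc_a"]],
    NADm_n = params$Nm_tot - y[["NADHm_n"]],
    NADm_a = params$Nm_tot - y[["NADHm_a"]],
    Cr_n = params$C_tot - y[["PCr_n"]],
    Cr_a = params$C_tot - y[["PCr_a"]])
}

#' @export
print.ngv_state <- function(x, ...) {
  cat("<ngv_state> (mM; cAMP_a uM)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

# Documented initial guess for the resting-state root solve; also persisted
# under [resting_guess] in inst/extdata/default_params.toml.
ngv_resting_guess <- function(params = ngv_default_params()) {
  y <- c(
    Na_n = 8, GLC_n = 1.0, G6P_n = 0.1, PYR_n = 0.1, LAC_n = 0.8,
    NADHc_n = 0.005, NADHm_n = 0.12, ATP_n = 2.2, PCr_n = 5, O2_n = 3,
    Na_a = 14, GLC_a = 1.1, G6P_a = 0.1, PYR_a = 0.15, LAC_a = 1.3,
    NADHc_a = 0.01, NADHm_a = 0.12, ATP_a = 2.2, PCr_a = 5, O2_a = 5,
    GLY_a = 7, cAMP_a = 0.05,
    GLU_e = 3e-5, GLC_e = 1.2, LAC_e = 1.0,
    GLC_c = 4.5, LAC_c = 0.7, O2_c = 7.5
  )
  y[NGV_SPECIES]
}
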