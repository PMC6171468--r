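# Model parameters for the neuro-glio-vascular (NGV) metabolic unit.
#
# Units: concentrations mM (cAMP in uM), time s, membrane fluxes expressed in
# the receiving compartment's volume frame (see ?ngv_derivatives for the frame
# table).  None of these numbers is a measured constant: they are documented,
# physiologically plausible defaults for the described architecture, and every
# one can be overridden from a TOML parameter file.

#' Default parameters of the NGV metabolic unit
#'
#' Returns the complete parameter set of the compartmental
#' neuron/astrocyte/ECS/capillary energy-metabolism model, as a named list of
#' class `ngv_params`.  Parameters are grouped by mechanism; suffix `_n` /
#' `_a` marks neuron / astrocyte copies of a cell-level constant.
#'
#' Key groups:
#' \describe{
#'   \item{pools}{`A_tot`, `Nc_tot`, `Nm_tot`, `C_tot` (mM): conserved
#'     adenine, cytosolic/mitochondrial NAD and creatine totals.  ADP, NAD+
#'     and Cr are derived, never stored.}
#'   \item{glut}{symmetric saturable glucose carriers, capillary to ECS
#'     (`T_glut_ce`) and ECS into each cell (`T_glut_en`, `T_glut_ea`),
#'     shared `K_glut`.}
#'   \item{hk}{lumped hexokinase--phosphofructokinase step, Hill-inhibited
#'     by ATP (`K_I_atp`, `n_H`) with saturable GLC and ATP substrate terms.}
#'   \item{pk}{lumped lower glycolysis, G6P to 2 pyruvate, producing
#'     2 ATP and 2 cytosolic NADH.}
#'   \item{ldh}{mass-action reversible lactate dehydrogenase; the astrocyte
#'     copy favors lactate production, the neuron copy lactate consumption.}
#'   \item{mito}{saturable TCA + oxidative-phosphorylation lump producing
#'     `n_atp_ox` ATP per pyruvate (the lump's internal TCA NADH is burned
#'     within the lump); `k_etc` re-oxidizes shuttle-delivered mitochondrial
#'     NADH at `n_atp_nadh` ATP and 1/2 O2 per NADH.}
#'   \item{transport/pump}{MCT lactate carriers, O2 permeability-surface
#'     products, Na/K ATPase (`k_pump`, 1 ATP per 3 Na), Na leak, AMPA Na
#'     influx gain, EAAT glutamate uptake with 3 Na per glutamate.}
#'   \item{glycogen}{glycogen synthase (capacity-limited by `GLY_max`) and
#'     phosphorylase activated by cAMP; noradrenaline drives cAMP synthesis.}
#'   \item{capillary}{arterial concentrations and the baseline exchange rate
#'     `F_0`; cerebral blood flow enters as a dimensionless multiplier of
#'     `F_0`.}
#'   \item{volumes}{volume fractions `v_n`, `v_a`, `v_e`, `v_c` (sum to 1).}
#' }
#'
#' @param ... named overrides applied on top of the defaults.
#' @return named list of class `ngv_params`.
#' @examples
#' p <- ngv_default_params(v_n = 0.4, v_a = 0.3)
#' p$A_tot
#' @export
ngv_default_params <- function(...) {
  p <- list(
    # conserved pools (mM)
    A_tot = 2.4, Nc_tot = 0.5, Nm_tot = 0.5, C_tot = 10,

    # glucose carriers (GLUT), symmetric saturable
    T_glut_ce = 0.12, T_glut_en = 0.5, T_glut_ea = 0.3, K_glut = 8,

    # hexokinase-PFK lump
    k_hk_n = 0.10, k_hk_a = 0.12, K_glc_hk = 0.05,
    K_I_atp = 1.0, n_H = 4, K_atp_hk = 0.1,

    # lower glycolysis lump (per mM G6P)
    k_pk_n = 0.08, k_pk_a = 0.08, K_adp_pk = 0.05, K_nad_pk = 0.05,

    # lactate dehydrogenase, mass action reversible (per mM^2)
    k_ldh_f_n = 5,  k_ldh_r_n = 0.003,
    k_ldh_f_a = 6,  k_ldh_r_a = 0.0003,

    # mitochondrial lump + electron transport of shuttle NADH
    V_mito_n = 0.09, V_mito_a = 0.008,
    K_pyr = 0.05, K_o2 = 0.01, K_adp = 0.1, K_nadm = 0.1,
    n_atp_ox = 14.8, o2_per_pyr = 3,
    k_etc_n = 0.2, k_etc_a = 0.05, n_atp_nadh = 2.5,

    # cytosol -> mitochondria NADH shuttle
    k_shuttle_n = 4, k_shuttle_a = 1,

    # monocarboxylate transporters (lactate)
    T_mct_n = 0.2, T_mct_a = 0.1, T_mct_ec = 0.25, K_mct = 1,

    # oxygen permeability-surface products (capillary -> cell)
    PS_o2_n = 0.05, PS_o2_a = 0.02,

    # Na/K pump, leak, AMPA, EAAT
    k_pump_n = 0.0114, k_pump_a = 0.0009,
    g_leak_n = 0.0042, g_leak_a = 0.0006,
    na_e = 150,
    g_ampa = 2,
    V_eaat = 0.15, K_glu = 0.02, s_na = 3,
    f_glu_recycle = 0.5, k_glu_decay = 0.1,

    # creatine kinase
    k_ck_f = 0.1, k_ck_r = 0.009,

    # glycogen
    V_gs = 0.005, K_gs = 0.1, GLY_max = 12, K_atp_gs = 0.1,
    V_gp = 0.02, K_gp = 1, K_camp = 1,

    # noradrenaline -> cAMP transduction (uM, uM/s)
    k_ne = 1, k_camp_basal = 0.005, k_camp_deg = 0.1,

    # capillary exchange
    GLC_art = 4.8, LAC_art = 0.6, O2_art = 8, F_0 = 0.6,

    # resting drive
    j_rel_rest = 1e-4,

    # volume fractions
    v_n = 0.45, v_a = 0.25, v_e = 0.2, v_c = 0.1,

    # mechanism switches used for closed-system conservation runs
    transport_off = FALSE, mito_off = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "ngv_params"
  validate_params(p)
  p
}

#' Validate an `ngv_params` object
#'
#' Checks positivity of rate constants and pool totals, the volume-fraction
#' sum, and the fixed 3-Na-per-glutamate EAAT stoichiometry.
#'
#' @param p parameter list as returned by [ngv_default_params()].
#' @return `p`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_params <- function(p) {
  num <- p[!(names(p) %in% c("transport_off", "mito_off"))]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "))
  positive <- c("A_tot", "Nc_tot", "Nm_tot", "C_tot", "K_glut", "K_mct",
                "K_I_atp", "n_H", "K_pyr", "K_o2", "K_adp", "K_nadm",
                "K_glu", "K_gs", "K_gp", "K_camp", "F_0", "GLY_max",
                "k_camp_deg", "na_e", "n_atp_ox")
  for (nm in positive)
    if (p[[nm]] <= 0) stop("parameter must be > 0: ", nm)
  nonneg <- setdiff(names(num), positive)
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter must be >= 0: ", nm)
  vsum <- p$v_n + p$v_a + p$v_e + p$v_c
  if (abs(vsum - 1) > 1e-9)
    stop("volume fractions v_n + v_a + v_e + v_c must sum to 1, got ", vsum)
  if (p$s_na != 3)
    stop("s_na (Na per glutamate on EAAT) is fixed at 3, got ", p$s_na)
  invisible(p)
}

#' @export
print.ngv_params <- function(x, ...) {
  cat("<ngv_params> ", length(x), " parameters\n", sep = "")
  cat("  pools (mM): A_tot=", x$A_tot, " Nc_tot=", x$Nc_tot,
      " Nm_tot=", x$Nm_tot, " C_tot=", x$C_tot, "\n", sep = "")
  cat("  volume fractions: n=", x$v_n, " a=", x$v_a,
      " e=", x$v_e, " c=", x$v_c, "\n", sep = "")
  cat("  switches: transport_off=", x$transport_off,
      ", mito_off=", x$mito_off, "\n", sep = "")
  invisible(x)
}

#' Read / write NGV parameters as TOML
#'
#' The parameter file is flat TOML: one `key = value` line per parameter,
#' grouped under mechanism tables whose headers are ignored on read (table
#' names only organize the file).  `write_params_toml()` emits the canonical
#' grouping.  Values absent from the file keep their defaults.
#'
#' @param path file path.
#' @param p parameters to write.
#' @return `read_params_toml()` returns an `ngv_params` list.
#' @seealso [ngv_default_params()]
#' @export
read_params_toml <- function(path) {
  kv <- read_toml(path)
  kv <- kv[!(names(kv) %in% c("resting_guess", "resting_state"))]
  flat <- flatten_toml(kv)
  do.call(ngv_default_params, flat)
}

#' @rdname read_params_toml
#' @export
write_params_toml <- function(p, path) {
  validate_params(p)
  groups <- list(
    pools = c("A_tot", "Nc_tot", "Nm_tot", "C_tot"),
    glut = c("T_glut_ce", "T_glut_en", "T_glut_ea", "K_glut"),
    hexokinase = c("k_hk_n", "k_hk_a", "K_glc_hk", "K_I_atp", "n_H", "K_atp_hk"),
    glycolysis = c("k_pk_n", "k_pk_a", "K_adp_pk", "K_nad_pk"),
    ldh = c("k_ldh_f_n", "k_ldh_r_n", "k_ldh_f_a", "k_ldh_r_a"),
    mito = c("V_mito_n", "V_mito_a", "K_pyr", "K_o2", "K_adp", "K_nadm",
             "n_atp_ox", "o2_per_pyr", "k_etc_n", "k_etc_a", "n_atp_nadh"),
    shuttle = c("k_shuttle_n", "k_shuttle_a"),
    mct = c("T_mct_n", "T_mct_a", "T_mct_ec", "K_mct"),
    oxygen = c("PS_o2_n", "PS_o2_a"),
    sodium = c("k_pump_n", "k_pump_a", "g_leak_n", "g_leak_a", "na_e",
               "g_ampa", "V_eaat", "K_glu", "s_na", "f_glu_recycle",
               "k_glu_decay"),
    creatine_kinase = c("k_ck_f", "k_ck_r"),
    glycogen = c("V_gs", "K_gs", "GLY_max", "K_atp_gs", "V_gp", "K_gp",
                 "K_camp"),
    noradrenaline = c("k_ne", "k_camp_basal", "k_camp_deg"),
    capillary = c("GLC_art", "LAC_art", "O2_art", "F_0"),
    drive = c("j_rel_rest"),
    volumes = c("v_n", "v_a", "v_e", "v_c"),
    switches = c("transport_off", "mito_off")
  )
  tabs <- lapply(groups, function(keys) p[keys])
  write_toml(tabs, path)
  invisible(path)
}
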