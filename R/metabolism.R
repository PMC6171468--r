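# Reaction network of the NGV metabolic unit: rate laws and stoichiometry.
#
# Rate-law conventions (documented once, here):
#   * reversible carriers use the symmetric saturable form
#       T * (S1/(S1+K) - S2/(S2+K)),
#     which is exactly 0 at zero gradient;
#   * LDH and creatine kinase are mass-action reversible;
#   * the hexokinase-PFK lump is Hill-inhibited by ATP and saturable in its
#     substrates, so every unidirectional term vanishes as its substrate
#     vanishes (positivity under exact integration);
#   * the mitochondrial lump is a product of saturating terms in PYR, O2,
#     ADP and mitochondrial NAD+ (the TCA electron acceptor); a separate
#     electron-transport term re-oxidizes shuttle-delivered mitochondrial
#     NADH with its own ATP yield and O2 cost.
#
# Volume frames: every trans-membrane flux is expressed in mM/s of the
# RECEIVING compartment at positive sign:
#   J_glut_ce  ECS frame        (capillary -> ECS glucose)
#   J_glut_en  neuron frame     (ECS -> neuron glucose)
#   J_glut_ea  astrocyte frame  (ECS -> astrocyte glucose)
#   J_mct_n/a  ECS frame        (positive = cell exports lactate to ECS)
#   J_mct_ec   capillary frame  (positive = ECS -> capillary lactate)
#   J_o2_n/a   cell frame       (capillary -> cell oxygen)
#   J_eaat     ECS frame        (glutamate removed from ECS)
#   J_ampa, J_pump, J_leak      cell frame (Na bookkeeping)
# Converting a flux J from frame B to frame A multiplies by v_B / v_A.

sat <- function(s, k) s / (s + k)

#' Compute all reaction and transport fluxes at one state
#'
#' Evaluates the full flux set of the NGV unit at state `y` under the
#' instantaneous external drive `drive_at_t`.  See the source header for rate
#' laws and volume-frame conventions.
#'
#' @param y state vector (see [ngv_state()]).
#' @param params model parameters.
#' @param drive_at_t list with elements `j_rel` (mM/s glutamate release into
#'   the ECS), `cbf` (dimensionless CBF multiple of `F_0`), `ne` (uM
#'   noradrenaline), and optionally `j_na_extra` (mM/s extra neuronal Na
#'   influx, the coupling hook for the Hodgkin-Huxley module).
#' @param validate check state invariants first (disabled on the integrator's
#'   hot path, which validates at output points instead).
#' @return named list of fluxes (mM/s, `J_camp` uM/s).
#' @export
compute_fluxes <- function(y, params, drive_at_t = list(j_rel = 0, cbf = 1, ne = 0),
                           validate = TRUE) {
  if (validate) validate_state(y, params)
  p <- params
  d <- ngv_derived(y, p)

  tr <- if (isTRUE(p$transport_off)) 0 else 1
  mi <- if (isTRUE(p$mito_off)) 0 else 1

  K <- p$K_glut
  J_glut_ce <- tr * p$T_glut_ce * (sat(y[["GLC_c"]], K) - sat(y[["GLC_e"]], K))
  J_glut_en <- tr * p$T_glut_en * (sat(y[["GLC_e"]], K) - sat(y[["GLC_n"]], K))
  J_glut_ea <- tr * p$T_glut_ea * (sat(y[["GLC_e"]], K) - sat(y[["GLC_a"]], K))

  hill_inh <- function(atp)
    p$K_I_atp^p$n_H / (p$K_I_atp^p$n_H + atp^p$n_H)
  J_hk_n <- p$k_hk_n * sat(y[["GLC_n"]], p$K_glc_hk) *
    hill_inh(y[["ATP_n"]]) * sat(y[["ATP_n"]], p$K_atp_hk)
  J_hk_a <- p$k_hk_a * sat(y[["GLC_a"]], p$K_glc_hk) *
    hill_inh(y[["ATP_a"]]) * sat(y[["ATP_a"]], p$K_atp_hk)

  J_pk_n <- p$k_pk_n * y[["G6P_n"]] * sat(d[["ADP_n"]], p$K_adp_pk) *
    sat(d[["NADc_n"]], p$K_nad_pk)
  J_pk_a <- p$k_pk_a * y[["G6P_a"]] * sat(d[["ADP_a"]], p$K_adp_pk) *
    sat(d[["NADc_a"]], p$K_nad_pk)

  J_ldh_n <- p$k_ldh_f_n * y[["PYR_n"]] * y[["NADHc_n"]] -
    p$k_ldh_r_n * y[["LAC_n"]] * d[["NADc_n"]]
  J_ldh_a <- p$k_ldh_f_a * y[["PYR_a"]] * y[["NADHc_a"]] -
    p$k_ldh_r_a * y[["LAC_a"]] * d[["NADc_a"]]

  J_mito_n <- mi * p$V_mito_n * sat(y[["PYR_n"]], p$K_pyr) *
    sat(y[["O2_n"]], p$K_o2) * sat(d[["ADP_n"]], p$K_adp) *
    sat(d[["NADm_n"]], p$K_nadm)
  J_mito_a <- mi * p$V_mito_a * sat(y[["PYR_a"]], p$K_pyr) *
    sat(y[["O2_a"]], p$K_o2) * sat(d[["ADP_a"]], p$K_adp) *
    sat(d[["NADm_a"]], p$K_nadm)

  # electron-transport oxidation of shuttle-delivered mitochondrial NADH:
  # the pyruvate lump is redox-neutral internally (its TCA NADH is produced
  # and burned within the lump); NADHm imported by the shuttle is re-oxidized
  # here at 1/2 O2 and n_atp_nadh ATP per NADH
  J_etc_n <- mi * p$k_etc_n * y[["NADHm_n"]] * sat(y[["O2_n"]], p$K_o2) *
    sat(d[["ADP_n"]], p$K_adp)
  J_etc_a <- mi * p$k_etc_a * y[["NADHm_a"]] * sat(y[["O2_a"]], p$K_o2) *
    sat(d[["ADP_a"]], p$K_adp)

  J_shuttle_n <- p$k_shuttle_n * y[["NADHc_n"]] * d[["NADm_n"]] / p$Nm_tot
  J_shuttle_a <- p$k_shuttle_a * y[["NADHc_a"]] * d[["NADm_a"]] / p$Nm_tot

  Km <- p$K_mct
  J_mct_n <- tr * p$T_mct_n * (sat(y[["LAC_n"]], Km) - sat(y[["LAC_e"]], Km))
  J_mct_a <- tr * p$T_mct_a * (sat(y[["LAC_a"]], Km) - sat(y[["LAC_e"]], Km))
  J_mct_ec <- tr * p$T_mct_ec * (sat(y[["LAC_e"]], Km) - sat(y[["LAC_c"]], Km))

  J_o2_n <- tr * p$PS_o2_n * (y[["O2_c"]] - y[["O2_n"]])
  J_o2_a <- tr * p$PS_o2_a * (y[["O2_c"]] - y[["O2_a"]])

  # Na/K ATPase: J_pump is the ATP consumption rate; 3 Na extruded per ATP
  J_pump_n <- p$k_pump_n * y[["ATP_n"]] * y[["Na_n"]]
  J_pump_a <- p$k_pump_a * y[["ATP_a"]] * y[["Na_a"]]
  J_leak_n <- p$g_leak_n * (p$na_e - y[["Na_n"]])
  J_leak_a <- p$g_leak_a * (p$na_e - y[["Na_a"]])

  glu <- y[["GLU_e"]]
  J_ampa <- p$g_ampa * glu * (p$na_e - y[["Na_n"]]) / p$na_e
  J_eaat <- p$V_eaat * sat(glu, p$K_glu)

  J_ck_n <- p$k_ck_f * y[["PCr_n"]] * d[["ADP_n"]] -
    p$k_ck_r * d[["Cr_n"]] * y[["ATP_n"]]
  J_ck_a <- p$k_ck_f * y[["PCr_a"]] * d[["ADP_a"]] -
    p$k_ck_r * d[["Cr_a"]] * y[["ATP_a"]]

  J_gs <- p$V_gs * sat(y[["G6P_a"]], p$K_gs) *
    max(0, 1 - y[["GLY_a"]] / p$GLY_max) * sat(y[["ATP_a"]], p$K_atp_gs)
  J_gp <- p$V_gp * sat(y[["GLY_a"]], p$K_gp) * sat(y[["cAMP_a"]], p$K_camp)

  ne <- if (is.null(drive_at_t$ne)) 0 else drive_at_t$ne
  J_camp <- p$k_ne * ne + p$k_camp_basal - p$k_camp_deg * y[["cAMP_a"]]

  cbf <- if (is.null(drive_at_t$cbf)) 1 else drive_at_t$cbf
  flow <- tr * cbf * p$F_0
  J_o2_cap <- flow * (p$O2_art - y[["O2_c"]])

  list(
    J_glut_ce = J_glut_ce, J_glut_en = J_glut_en, J_glut_ea = J_glut_ea,
    J_hk_n = J_hk_n, J_hk_a = J_hk_a,
    J_pk_n = J_pk_n, J_pk_a = J_pk_a,
    J_ldh_n = J_ldh_n, J_ldh_a = J_ldh_a,
    J_mct_n = J_mct_n, J_mct_a = J_mct_a, J_mct_ec = J_mct_ec,
    J_mito_n = J_mito_n, J_mito_a = J_mito_a,
    J_etc_n = J_etc_n, J_etc_a = J_etc_a,
    J_shuttle_n = J_shuttle_n, J_shuttle_a = J_shuttle_a,
    J_pump_n = J_pump_n, J_pump_a = J_pump_a,
    J_leak_n = J_leak_n, J_leak_a = J_leak_a,
    J_ampa = J_ampa, J_eaat = J_eaat,
    J_ck_n = J_ck_n, J_ck_a = J_ck_a,
    J_gs = J_gs, J_gp = J_gp,
    J_o2_n = J_o2_n, J_o2_a = J_o2_a, J_o2_cap = J_o2_cap,
    J_camp = J_camp,
    flow = flow
  )
}

#' Time derivative of the NGV state
#'
#' Assembles the stoichiometry over the fluxes of [compute_fluxes()]:
#' 1 GLC -> 1 G6P (costs 1 ATP); 1 G6P -> 2 PYR (+2 ATP, +2 NADHc);
#' PYR + NADHc <-> LAC + NAD+; the mitochondrial lump burns 1 PYR and
#' `o2_per_pyr` O2, yields `n_atp_ox` ATP and re-oxidizes `nadh_per_pyr`
#' shuttle-delivered NADHm; the pump costs 1 ATP per 3 Na; PCr + ADP <->
#' Cr + ATP; glycogen exchanges with G6P_a (phosphorylase yields G6P without
#' ATP cost at this lumping); capillary species relax toward arterial values
#' at rate CBF*F_0.  Volume-fraction conversions follow the frame table in
#' the source header of [compute_fluxes()].
#'
#' @inheritParams compute_fluxes
#' @param fluxes optionally, a precomputed result of [compute_fluxes()].
#' @return named numeric vector d(state)/dt, mM/s (`cAMP_a` uM/s).
#' @export
ngv_derivatives <- function(y, params, drive_at_t = list(j_rel = 0, cbf = 1, ne = 0),
                            fluxes = NULL) {
  p <- params
  f <- if (is.null(fluxes)) compute_fluxes(y, p, drive_at_t) else fluxes

  j_rel <- if (is.null(drive_at_t$j_rel)) 0 else drive_at_t$j_rel
  j_na_extra <- if (is.null(drive_at_t$j_na_extra)) 0 else drive_at_t$j_na_extra

  v_n <- p$v_n; v_a <- p$v_a; v_e <- p$v_e; v_c <- p$v_c

  dy <- c(
    Na_n = f$J_leak_n + f$J_ampa + j_na_extra - 3 * f$J_pump_n,
    GLC_n = f$J_glut_en - f$J_hk_n,
    G6P_n = f$J_hk_n - f$J_pk_n,
    PYR_n = 2 * f$J_pk_n - f$J_ldh_n - f$J_mito_n,
    LAC_n = f$J_ldh_n - f$J_mct_n * v_e / v_n,
    NADHc_n = 2 * f$J_pk_n - f$J_ldh_n - f$J_shuttle_n,
    NADHm_n = f$J_shuttle_n - f$J_etc_n,
    ATP_n = -f$J_hk_n + 2 * f$J_pk_n + p$n_atp_ox * f$J_mito_n +
      p$n_atp_nadh * f$J_etc_n - f$J_pump_n + f$J_ck_n,
    PCr_n = -f$J_ck_n,
    O2_n = f$J_o2_n - p$o2_per_pyr * f$J_mito_n - 0.5 * f$J_etc_n,

    Na_a = f$J_leak_a + p$s_na * f$J_eaat * v_e / v_a - 3 * f$J_pump_a,
    GLC_a = f$J_glut_ea - f$J_hk_a,
    G6P_a = f$J_hk_a - f$J_pk_a + f$J_gp - f$J_gs,
    PYR_a = 2 * f$J_pk_a - f$J_ldh_a - f$J_mito_a,
    LAC_a = f$J_ldh_a - f$J_mct_a * v_e / v_a,
    NADHc_a = 2 * f$J_pk_a - f$J_ldh_a - f$J_shuttle_a,
    NADHm_a = f$J_shuttle_a - f$J_etc_a,
    ATP_a = -f$J_hk_a + 2 * f$J_pk_a + p$n_atp_ox * f$J_mito_a +
      p$n_atp_nadh * f$J_etc_a - f$J_pump_a + f$J_ck_a - f$J_gs,
    PCr_a = -f$J_ck_a,
    O2_a = f$J_o2_a - p$o2_per_pyr * f$J_mito_a - 0.5 * f$J_etc_a,

    GLY_a = f$J_gs - f$J_gp,
    cAMP_a = f$J_camp,

    GLU_e = j_rel - (1 - p$f_glu_recycle) * f$J_eaat -
      p$k_glu_decay * y[["GLU_e"]],
    GLC_e = f$J_glut_ce - (f$J_glut_en * v_n + f$J_glut_ea * v_a) / v_e,
    LAC_e = f$J_mct_n + f$J_mct_a - f$J_mct_ec * v_c / v_e,

    GLC_c = f$flow * (p$GLC_art - y[["GLC_c"]]) - f$J_glut_ce * v_e / v_c,
    LAC_c = f$flow * (p$LAC_art - y[["LAC_c"]]) + f$J_mct_ec,
    O2_c = f$J_o2_cap - (f$J_o2_n * v_n + f$J_o2_a * v_a) / v_c
  )
  dy
}

# Fast right-hand-side factory for integration.  Binds every parameter into
# a local and works positionally on an unnamed state vector, mirroring
# compute_fluxes()/ngv_derivatives() exactly; the two paths are asserted
# equal in the test suite so they cannot drift apart silently.
ngv_rhs_factory <- function(params, drive) {
  p <- params
  force(drive)
  j_rel_f <- drive$j_rel; cbf_f <- drive$cbf; ne_f <- drive$ne
  na_extra_f <- drive$j_na_extra

  tr <- if (isTRUE(p$transport_off)) 0 else 1
  mi <- if (isTRUE(p$mito_off)) 0 else 1
  A_tot <- p$A_tot; Nc_tot <- p$Nc_tot; Nm_tot <- p$Nm_tot; C_tot <- p$C_tot
  T_glut_ce <- tr * p$T_glut_ce; T_glut_en <- tr * p$T_glut_en
  T_glut_ea <- tr * p$T_glut_ea; K_glut <- p$K_glut
  k_hk_n <- p$k_hk_n; k_hk_a <- p$k_hk_a; K_glc_hk <- p$K_glc_hk
  KI_pow <- p$K_I_atp^p$n_H; n_H <- p$n_H; K_atp_hk <- p$K_atp_hk
  k_pk_n <- p$k_pk_n; k_pk_a <- p$k_pk_a
  K_adp_pk <- p$K_adp_pk; K_nad_pk <- p$K_nad_pk
  k_ldh_f_n <- p$k_ldh_f_n; k_ldh_r_n <- p$k_ldh_r_n
  k_ldh_f_a <- p$k_ldh_f_a; k_ldh_r_a <- p$k_ldh_r_a
  V_mito_n <- mi * p$V_mito_n; V_mito_a <- mi * p$V_mito_a
  K_pyr <- p$K_pyr; K_o2 <- p$K_o2; K_adp <- p$K_adp; K_nadm <- p$K_nadm
  n_atp_ox <- p$n_atp_ox; o2_per_pyr <- p$o2_per_pyr
  k_etc_n <- mi * p$k_etc_n; k_etc_a <- mi * p$k_etc_a
  n_atp_nadh <- p$n_atp_nadh
  k_shuttle_n <- p$k_shuttle_n; k_shuttle_a <- p$k_shuttle_a
  T_mct_n <- tr * p$T_mct_n; T_mct_a <- tr * p$T_mct_a
  T_mct_ec <- tr * p$T_mct_ec; K_mct <- p$K_mct
  PS_o2_n <- tr * p$PS_o2_n; PS_o2_a <- tr * p$PS_o2_a
  k_pump_n <- p$k_pump_n; k_pump_a <- p$k_pump_a
  g_leak_n <- p$g_leak_n; g_leak_a <- p$g_leak_a; na_e <- p$na_e
  g_ampa <- p$g_ampa; V_eaat <- p$V_eaat; K_glu <- p$K_glu; s_na <- p$s_na
  f_rec <- p$f_glu_recycle; k_glu_decay <- p$k_glu_decay
  k_ck_f <- p$k_ck_f; k_ck_r <- p$k_ck_r
  V_gs <- p$V_gs; K_gs <- p$K_gs; GLY_max <- p$GLY_max; K_atp_gs <- p$K_atp_gs
  V_gp <- p$V_gp; K_gp <- p$K_gp; K_camp <- p$K_camp
  k_ne <- p$k_ne; k_camp_basal <- p$k_camp_basal; k_camp_deg <- p$k_camp_deg
  GLC_art <- p$GLC_art; LAC_art <- p$LAC_art; O2_art <- p$O2_art; F_0 <- p$F_0
  v_n <- p$v_n; v_a <- p$v_a; v_e <- p$v_e; v_c <- p$v_c
  tr_flag <- tr

  function(t, y) {
    Na_n <- y[[1L]]; GLC_n <- y[[2L]]; G6P_n <- y[[3L]]; PYR_n <- y[[4L]]
    LAC_n <- y[[5L]]; NADHc_n <- y[[6L]]; NADHm_n <- y[[7L]]; ATP_n <- y[[8L]]
    PCr_n <- y[[9L]]; O2_n <- y[[10L]]
    Na_a <- y[[11L]]; GLC_a <- y[[12L]]; G6P_a <- y[[13L]]; PYR_a <- y[[14L]]
    LAC_a <- y[[15L]]; NADHc_a <- y[[16L]]; NADHm_a <- y[[17L]]; ATP_a <- y[[18L]]
    PCr_a <- y[[19L]]; O2_a <- y[[20L]]
    GLY_a <- y[[21L]]; cAMP_a <- y[[22L]]
    GLU_e <- y[[23L]]; GLC_e <- y[[24L]]; LAC_e <- y[[25L]]
    GLC_c <- y[[26L]]; LAC_c <- y[[27L]]; O2_c <- y[[28L]]

    ADP_n <- A_tot - ATP_n; ADP_a <- A_tot - ATP_a
    NADc_n <- Nc_tot - NADHc_n; NADc_a <- Nc_tot - NADHc_a
    NADm_n <- Nm_tot - NADHm_n; NADm_a <- Nm_tot - NADHm_a
    Cr_n <- C_tot - PCr_n; Cr_a <- C_tot - PCr_a

    J_glut_ce <- T_glut_ce * (GLC_c / (GLC_c + K_glut) - GLC_e / (GLC_e + K_glut))
    J_glut_en <- T_glut_en * (GLC_e / (GLC_e + K_glut) - GLC_n / (GLC_n + K_glut))
    J_glut_ea <- T_glut_ea * (GLC_e / (GLC_e + K_glut) - GLC_a / (GLC_a + K_glut))

    J_hk_n <- k_hk_n * GLC_n / (GLC_n + K_glc_hk) *
      KI_pow / (KI_pow + ATP_n^n_H) * ATP_n / (ATP_n + K_atp_hk)
    J_hk_a <- k_hk_a * GLC_a / (GLC_a + K_glc_hk) *
      KI_pow / (KI_pow + ATP_a^n_H) * ATP_a / (ATP_a + K_atp_hk)

    J_pk_n <- k_pk_n * G6P_n * ADP_n / (ADP_n + K_adp_pk) *
      NADc_n / (NADc_n + K_nad_pk)
    J_pk_a <- k_pk_a * G6P_a * ADP_a / (ADP_a + K_adp_pk) *
      NADc_a / (NADc_a + K_nad_pk)

    J_ldh_n <- k_ldh_f_n * PYR_n * NADHc_n - k_ldh_r_n * LAC_n * NADc_n
    J_ldh_a <- k_ldh_f_a * PYR_a * NADHc_a - k_ldh_r_a * LAC_a * NADc_a

    J_mito_n <- V_mito_n * PYR_n / (PYR_n + K_pyr) * O2_n / (O2_n + K_o2) *
      ADP_n / (ADP_n + K_adp) * NADm_n / (NADm_n + K_nadm)
    J_mito_a <- V_mito_a * PYR_a / (PYR_a + K_pyr) * O2_a / (O2_a + K_o2) *
      ADP_a / (ADP_a + K_adp) * NADm_a / (NADm_a + K_nadm)

    J_etc_n <- k_etc_n * NADHm_n * O2_n / (O2_n + K_o2) * ADP_n / (ADP_n + K_adp)
    J_etc_a <- k_etc_a * NADHm_a * O2_a / (O2_a + K_o2) * ADP_a / (ADP_a + K_adp)

    J_shuttle_n <- k_shuttle_n * NADHc_n * NADm_n / Nm_tot
    J_shuttle_a <- k_shuttle_a * NADHc_a * NADm_a / Nm_tot

    J_mct_n <- T_mct_n * (LAC_n / (LAC_n + K_mct) - LAC_e / (LAC_e + K_mct))
    J_mct_a <- T_mct_a * (LAC_a / (LAC_a + K_mct) - LAC_e / (LAC_e + K_mct))
    J_mct_ec <- T_mct_ec * (LAC_e / (LAC_e + K_mct) - LAC_c / (LAC_c + K_mct))

    J_o2_n <- PS_o2_n * (O2_c - O2_n)
    J_o2_a <- PS_o2_a * (O2_c - O2_a)

    J_pump_n <- k_pump_n * ATP_n * Na_n
    J_pump_a <- k_pump_a * ATP_a * Na_a
    J_leak_n <- g_leak_n * (na_e - Na_n)
    J_leak_a <- g_leak_a * (na_e - Na_a)

    J_ampa <- g_ampa * GLU_e * (na_e - Na_n) / na_e
    J_eaat <- V_eaat * GLU_e / (GLU_e + K_glu)

    J_ck_n <- k_ck_f * PCr_n * ADP_n - k_ck_r * Cr_n * ATP_n
    J_ck_a <- k_ck_f * PCr_a * ADP_a - k_ck_r * Cr_a * ATP_a

    J_gs <- V_gs * G6P_a / (G6P_a + K_gs) * max(0, 1 - GLY_a / GLY_max) *
      ATP_a / (ATP_a + K_atp_gs)
    J_gp <- V_gp * GLY_a / (GLY_a + K_gp) * cAMP_a / (cAMP_a + K_camp)

    ne <- ne_f(t)
    J_camp <- k_ne * ne + k_camp_basal - k_camp_deg * cAMP_a

    flow <- tr_flag * cbf_f(t) * F_0
    J_o2_cap <- flow * (O2_art - O2_c)

    j_rel <- j_rel_f(t)
    j_na_extra <- if (is.null(na_extra_f)) 0 else na_extra_f(t)

    c(J_leak_n + J_ampa + j_na_extra - 3 * J_pump_n,
      J_glut_en - J_hk_n,
      J_hk_n - J_pk_n,
      2 * J_pk_n - J_ldh_n - J_mito_n,
      J_ldh_n - J_mct_n * v_e / v_n,
      2 * J_pk_n - J_ldh_n - J_shuttle_n,
      J_shuttle_n - J_etc_n,
      -J_hk_n + 2 * J_pk_n + n_atp_ox * J_mito_n + n_atp_nadh * J_etc_n -
        J_pump_n + J_ck_n,
      -J_ck_n,
      J_o2_n - o2_per_pyr * J_mito_n - 0.5 * J_etc_n,
      J_leak_a + s_na * J_eaat * v_e / v_a - 3 * J_pump_a,
      J_glut_ea - J_hk_a,
      J_hk_a - J_pk_a + J_gp - J_gs,
      2 * J_pk_a - J_ldh_a - J_mito_a,
      J_ldh_a - J_mct_a * v_e / v_a,
      2 * J_pk_a - J_ldh_a - J_shuttle_a,
      J_shuttle_a - J_etc_a,
      -J_hk_a + 2 * J_pk_a + n_atp_ox * J_mito_a + n_atp_nadh * J_etc_a -
        J_pump_a + J_ck_a - J_gs,
      -J_ck_a,
      J_o2_a - o2_per_pyr * J_mito_a - 0.5 * J_etc_a,
      J_gs - J_gp,
      J_camp,
      j_rel - (1 - f_rec) * J_eaat - k_glu_decay * GLU_e,
      J_glut_ce - (J_glut_en * v_n + J_glut_ea * v_a) / v_e,
      J_mct_n + J_mct_a - J_mct_ec * v_c / v_e,
      flow * (GLC_art - GLC_c) - J_glut_ce * v_e / v_c,
      flow * (LAC_art - LAC_c) + J_mct_ec,
      J_o2_cap - (J_o2_n * v_n + J_o2_a * v_a) / v_c)
  }
}
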