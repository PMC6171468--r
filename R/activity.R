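# Electrical activity: a classic squid-axon Hodgkin-Huxley membrane whose
# reversal potentials are recomputed continuously from ion concentrations via
# the Nernst equation, plus a spike-to-glutamate-release converter.  This is
# the optional electrical front end of the metabolic unit: spikes become
# exponential glutamate release transients, and the Na entering during
# spiking can be fed back to the metabolic model as an extra Na influx.

#' Nernst reversal potential
#'
#' `E = (R*T)/(z*F) * ln(c_out/c_in)`, in mV.
#'
#' @param z ionic valence (non-zero integer).
#' @param c_out,c_in outside / inside concentrations (mM, > 0).
#' @param T_K absolute temperature (K).
#' @return potential in mV.
#' @examples
#' nernst(1, 140, 14, T_K = 310)  # ~ +61.5 mV
#' @export
nernst <- function(z, c_out, c_in, T_K = 310) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("nernst: concentrations must be > 0")
  if (any(z == 0)) stop("nernst: valence must be non-zero")
  if (any(T_K <= 0)) stop("nernst: temperature must be > 0")
  R <- 8.314462618   # J/(mol K)
  F <- 96485.33212   # C/mol
  1000 * R * T_K / (z * F) * log(c_out / c_in)
}

# standard squid-axon rate functions (V in mV, rates in 1/ms)
hh_rates <- function(V) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  list(
    am = 0.1 * vtrap(-(V + 40), 10),
    bm = 4 * exp(-(V + 65) / 18),
    ah = 0.07 * exp(-(V + 65) / 20),
    bh = 1 / (1 + exp(-(V + 35) / 10)),
    an = 0.01 * vtrap(-(V + 55), 10),
    bn = 0.125 * exp(-(V + 65) / 80)
  )
}

#' Default Hodgkin-Huxley membrane constants
#'
#' Classic squid-axon constants: capacitance 1 uF/cm2, conductances
#' `g_na` 120, `g_k` 36, `g_l` 0.3 mS/cm2, leak reversal -54.4 mV; fixed
#' potassium concentrations for the (flag-gated) dynamic E_K; extracellular
#' Na 150 mM for E_Na; Nernst temperature 310 K.
#'
#' @return named list of constants.
#' @export
hh_default_constants <- function() {
  list(c_m = 1, g_na = 120, g_k = 36, g_l = 0.3, e_l = -54.387,
       na_out = 150, k_out = 5, k_in = 140, T_K = 310,
       e_k_fixed = -77)
}

#' Initial membrane state at rest
#'
#' Gating variables at their steady-state values for `V = -65` mV; reversal
#' potentials computed from the supplied Na concentration.
#'
#' @param na_in intracellular Na (mM) used for E_Na.
#' @param constants see [hh_default_constants()].
#' @param dynamic_e_k recompute E_K from the fixed K concentrations instead
#'   of using the constant `e_k_fixed`.
#' @return list with `V`, `m`, `h`, `n`, `E_Na`, `E_K`.
#' @export
hh_rest_state <- function(na_in = 8, constants = hh_default_constants(),
                          dynamic_e_k = FALSE) {
  V <- -65
  r <- hh_rates(V)
  list(V = V,
       m = r$am / (r$am + r$bm),
       h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn),
       E_Na = nernst(1, constants$na_out, na_in, constants$T_K),
       E_K = if (dynamic_e_k)
         nernst(1, constants$k_out, constants$k_in, constants$T_K)
       else constants$e_k_fixed)
}

#' One Hodgkin-Huxley time step
#'
#' Advances the membrane by `dt` ms (forward Euler on V and gating, the
#' standard discretization at this step size) with E_Na recomputed from the
#' current intracellular Na.  A spike is flagged on an upward crossing of
#' 0 mV.
#'
#' @param mem membrane state (see [hh_rest_state()]).
#' @param i_ext injected current (uA/cm2).
#' @param na_in intracellular Na (mM; e.g. `Na_n` of the metabolic state).
#' @param dt time step (ms, must be <= 0.025).
#' @param constants membrane constants.
#' @param dynamic_e_k recompute E_K each step (requires K concentrations in
#'   `constants`).
#' @return list: updated membrane state plus `spike` (logical) and `i_na`
#'   (Na current, uA/cm2, negative = inward).
#' @export
hh_step <- function(mem, i_ext, na_in, dt = 0.01,
                    constants = hh_default_constants(),
                    dynamic_e_k = FALSE) {
  if (dt > 0.025) stop("hh_step: dt must be <= 0.025 ms")
  if (!all(is.finite(c(mem$V, mem$m, mem$h, mem$n, i_ext, na_in))))
    stop("hh_step: non-finite membrane state or input")
  E_Na <- nernst(1, constants$na_out, na_in, constants$T_K)
  E_K <- if (dynamic_e_k)
    nernst(1, constants$k_out, constants$k_in, constants$T_K)
  else constants$e_k_fixed
  V <- mem$V
  r <- hh_rates(V)
  m <- mem$m + dt * (r$am * (1 - mem$m) - r$bm * mem$m)
  h <- mem$h + dt * (r$ah * (1 - mem$h) - r$bh * mem$h)
  n <- mem$n + dt * (r$an * (1 - mem$n) - r$bn * mem$n)
  m <- min(max(m, 0), 1); h <- min(max(h, 0), 1); n <- min(max(n, 0), 1)
  i_na <- constants$g_na * mem$m^3 * mem$h * (V - E_Na)
  i_k <- constants$g_k * mem$n^4 * (V - E_K)
  i_l <- constants$g_l * (V - constants$e_l)
  V_new <- V + dt * (i_ext - i_na - i_k - i_l) / constants$c_m
  list(V = V_new, m = m, h = h, n = n, E_Na = E_Na, E_K = E_K,
       spike = (V < 0 && V_new >= 0), i_na = i_na)
}

#' Simulate a Hodgkin-Huxley membrane over time
#'
#' Fixed-step simulation built on [hh_step()]; records the voltage trace,
#' spike times and the cumulative Na influx (available as a coupling flux for
#' the metabolic unit).
#'
#' @param i_ext_fun function(t_ms) -> injected current (uA/cm2).
#' @param t_max_ms duration (ms).
#' @param dt time step (ms, <= 0.025).
#' @param na_in intracellular Na (mM), held fixed unless `na_in_fun` given.
#' @param na_in_fun optional function(t_ms) -> Na_in, for coupled runs.
#' @param constants,dynamic_e_k see [hh_step()].
#' @return list: `t` (ms), `V` (mV), `spike_times` (ms), `gating` (matrix m,
#'   h, n), `na_influx` (mM-equivalent Na charge entry per unit membrane,
#'   arbitrary scale, for coupling).
#' @export
hh_simulate <- function(i_ext_fun, t_max_ms, dt = 0.01, na_in = 8,
                        na_in_fun = NULL, constants = hh_default_constants(),
                        dynamic_e_k = FALSE) {
  n_steps <- ceiling(t_max_ms / dt)
  tt <- numeric(n_steps + 1)
  VV <- numeric(n_steps + 1)
  gating <- matrix(NA_real_, n_steps + 1, 3, dimnames = list(NULL, c("m", "h", "n")))
  mem <- hh_rest_state(if (is.null(na_in_fun)) na_in else na_in_fun(0),
                       constants, dynamic_e_k)
  VV[1] <- mem$V
  gating[1, ] <- c(mem$m, mem$h, mem$n)
  spike_times <- numeric(0)
  na_influx <- 0
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    na <- if (is.null(na_in_fun)) na_in else na_in_fun(t)
    mem <- hh_step(mem, i_ext_fun(t), na, dt, constants, dynamic_e_k)
    tt[i + 1] <- i * dt
    VV[i + 1] <- mem$V
    gating[i + 1, ] <- c(mem$m, mem$h, mem$n)
    if (mem$spike) spike_times <- c(spike_times, i * dt)
    if (mem$i_na < 0) na_influx <- na_influx - mem$i_na * dt
  }
  list(t = tt, V = VV, spike_times = spike_times, gating = gating,
       na_influx = na_influx)
}

#' Glutamate release series from a spike train
#'
#' Each spike at time `t_k` contributes an exponential release transient
#' `(q/tau_rel) * exp(-(t - t_k)/tau_rel)` for `t >= t_k`, so the total
#' glutamate released per spike integrates to exactly `q`; overlapping
#' transients superpose.
#'
#' @param spike_times sorted spike times (s).
#' @param q quantal glutamate per spike (mM, >= 0).
#' @param tau_rel release time constant (s, > 0); default 2 ms.
#' @return function(t) -> J_rel(t) (mM/s), vectorized over `t`.
#' @export
release_from_spikes <- function(spike_times, q, tau_rel = 0.002) {
  if (q < 0) stop("release_from_spikes: q must be >= 0")
  if (tau_rel <= 0) stop("release_from_spikes: tau_rel must be > 0")
  if (is.unsorted(spike_times))
    stop("release_from_spikes: spike times must be sorted")
  tk <- spike_times
  function(t) {
    out <- numeric(length(t))
    for (k in seq_along(tk)) {
      on <- t >= tk[k]
      out[on] <- out[on] + (q / tau_rel) * exp(-(t[on] - tk[k]) / tau_rel)
    }
    out
  }
}
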