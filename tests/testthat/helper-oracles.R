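# Independent oracles used across the suite.  These deliberately avoid the
# package's accelerated code paths: fixed-step integrators written here from
# the Butcher tableau, and exhaustive no-pruning geometry scans.

# ---- fixed-step RK4 oracle over the package's reaction derivatives --------

rk4_oracle <- function(state0, params, drive, t_max, dt, keep_every) {
  rhs <- gliaflux:::ngv_rhs_factory(params, drive)
  y <- unname(unclass(state0))
  n_steps <- round(t_max / dt)
  n_keep <- floor(n_steps / keep_every) + 1L
  keep <- matrix(NA_real_, n_keep, length(y))
  keep[1, ] <- y
  ki <- 2L
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (i %% keep_every == 0L) {
      keep[ki, ] <- y
      ki <- ki + 1L
    }
  }
  colnames(keep) <- ngv_species()
  keep
}

# ---- independent Hodgkin-Huxley oracle (RK4 on the same kinetics) ---------

hh_oracle_spikes <- function(i_ext_fun, t_max_ms, dt = 0.005, na_in = 8) {
  cst <- hh_default_constants()
  e_na <- nernst(1, cst$na_out, na_in, cst$T_K)
  deriv <- function(t, s) {
    V <- s[1]; m <- s[2]; h <- s[3]; n <- s[4]
    r <- gliaflux:::hh_rates(V)
    i_na <- cst$g_na * m^3 * h * (V - e_na)
    i_k <- cst$g_k * n^4 * (V - cst$e_k_fixed)
    i_l <- cst$g_l * (V - cst$e_l)
    c((i_ext_fun(t) - i_na - i_k - i_l) / cst$c_m,
      r$am * (1 - m) - r$bm * m,
      r$ah * (1 - h) - r$bh * h,
      r$an * (1 - n) - r$bn * n)
  }
  r0 <- gliaflux:::hh_rates(-65)
  s <- c(-65, r0$am / (r0$am + r0$bm), r0$ah / (r0$ah + r0$bh),
         r0$an / (r0$an + r0$bn))
  n_steps <- round(t_max_ms / dt)
  spikes <- numeric(0)
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- deriv(t, s)
    k2 <- deriv(t + dt / 2, s + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, s + dt / 2 * k2)
    k4 <- deriv(t + dt, s + dt * k3)
    s_new <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s[1] < 0 && s_new[1] >= 0) spikes <- c(spikes, t + dt)
    s <- s_new
    t <- t + dt
  }
  spikes
}

# ---- exhaustive geometry oracles (no pruning, no acceleration) ------------

brute_dist_point_mesh <- function(p, m) {
  tv <- gliaflux:::tri_vertices(m)
  sqrt(min(gliaflux:::point_triangles_closest(p, tv$V1, tv$V2, tv$V3)$d2))
}

brute_contact_area <- function(a, b, epsilon) {
  cen <- tri_centroids(a)
  ar <- tri_areas(a)
  total <- 0
  for (i in seq_len(nrow(cen))) {
    if (brute_dist_point_mesh(cen[i, ], b) <= epsilon) total <- total + ar[i]
  }
  total
}

brute_min_distance <- function(a, b) {
  tva <- gliaflux:::tri_vertices(a)
  tvb <- gliaflux:::tri_vertices(b)
  best <- Inf
  for (i in seq_len(nrow(a$faces))) {
    Ti <- rbind(tva$V1[i, ], tva$V2[i, ], tva$V3[i, ])
    for (j in seq_len(nrow(b$faces))) {
      Tj <- rbind(tvb$V1[j, ], tvb$V2[j, ], tvb$V3[j, ])
      d <- gliaflux:::tri_tri_dist(Ti, Tj)
      if (d < best) best <- d
    }
  }
  best
}

# ---- shared fixtures ------------------------------------------------------

default_params_cached <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- ngv_default_params()
    p
  }
})

resting_state_cached <- local({
  rs <- NULL
  function() {
    if (is.null(rs)) rs <<- resting_state(default_params_cached())
    rs
  }
})

small_scene <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) {
      rec <- scene_recipe(n_axons = 2, n_dendrites = 1, n_boutons = 3,
                          n_spines = 2, n_astro_blobs = 2, box = 10,
                          subdiv = 1, n_seg = 8, seed = 7)
      sc <<- make_neuropil(rec)
    }
    sc
  }
})
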