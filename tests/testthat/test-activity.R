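# Hodgkin-Huxley membrane, Nernst reversals, spike-to-release conversion.

test_that("nernst matches the closed form and its symmetries", {
  rt_f <- 1000 * 8.314462618 * 310 / 96485.33212
  expect_equal(nernst(1, 140, 14, 310), rt_f * log(10), tolerance = 1e-12)
  expect_identical(nernst(1, 5, 5), 0)
  # valence scaling and antisymmetry
  expect_equal(nernst(2, 140, 14, 310), nernst(1, 140, 14, 310) / 2)
  for (pair in list(c(10, 3), c(150, 12), c(2, 90)))
    expect_equal(nernst(1, pair[1], pair[2]), -nernst(1, pair[2], pair[1]))
  expect_error(nernst(1, 0, 5), "> 0")
  expect_error(nernst(0, 5, 5), "valence")
})

test_that("membrane stays quiet at rest and spikes like the oracle under current", {
  r0 <- hh_simulate(function(t) 0, 100)
  expect_length(r0$spike_times, 0)
  expect_lt(max(abs(r0$V - r0$V[1])), 2)  # settles near rest

  r1 <- hh_simulate(function(t) 10, 100)
  expect_gte(length(r1$spike_times), 1)
  oracle <- hh_oracle_spikes(function(t) 10, 100)
  expect_equal(length(r1$spike_times), length(oracle))
  expect_equal(r1$spike_times, oracle, tolerance = 0.05)

  # refractoriness: two suprathreshold 1 ms pulses 2 ms apart -> one spike
  pulse2 <- function(t) ifelse((t >= 5 & t < 6) | (t >= 8 & t < 9), 30, 0)
  r2 <- hh_simulate(pulse2, 30)
  expect_equal(length(r2$spike_times), length(hh_oracle_spikes(pulse2, 30)))
  expect_length(r2$spike_times, 1)
})

test_that("gating variables remain in [0,1] and runs are deterministic", {
  r <- hh_simulate(function(t) ifelse(t > 10, 15, 0), 60)
  expect_true(all(r$gating >= 0 & r$gating <= 1))
  r2 <- hh_simulate(function(t) ifelse(t > 10, 15, 0), 60)
  expect_identical(r$V, r2$V)
  expect_identical(r$spike_times, r2$spike_times)
  expect_error(hh_step(hh_rest_state(), 0, 8, dt = 0.05), "0.025")
})

test_that("reversal potential tracks intracellular sodium", {
  cst <- hh_default_constants()
  s_lo <- hh_rest_state(na_in = 5, cst)
  s_hi <- hh_rest_state(na_in = 20, cst)
  expect_gt(s_lo$E_Na, s_hi$E_Na)
  stepped <- hh_step(s_lo, 0, na_in = 20)
  expect_equal(stepped$E_Na, nernst(1, cst$na_out, 20, cst$T_K))
})

test_that("release kernel integrates to q per spike and superposes", {
  j0 <- release_from_spikes(numeric(0), q = 0.1)
  expect_identical(j0(seq(0, 1, 0.01)), rep(0, 101))

  # single spike at t = 0: the kernel is smooth on [0, T], so trapezoid
  # quadrature resolves the normalization to ~1e-8 relative
  tq <- seq(0, 0.06, 1e-6)
  j1 <- release_from_spikes(0, q = 0.05, tau_rel = 0.002)
  jj <- j1(tq)
  integral <- sum((jj[-1] + jj[-length(jj)]) / 2) * 1e-6
  expect_equal(integral, 0.05, tolerance = 1e-6)
  # multi-spike trains superpose exactly, so the train integral is n*q
  tt <- seq(0, 2, 1e-4)
  j3 <- release_from_spikes(c(0.1, 0.5, 0.9), q = 0.05, tau_rel = 0.002)
  parts <- lapply(c(0.1, 0.5, 0.9), function(tk)
    release_from_spikes(tk, q = 0.05, tau_rel = 0.002)(tt))
  expect_equal(j3(tt), parts[[1]] + parts[[2]] + parts[[3]], tolerance = 1e-15)
  j2 <- release_from_spikes(c(0.3, 0.3), q = 0.05)
  expect_equal(j2(tt), 2 * release_from_spikes(0.3, q = 0.05)(tt))

  expect_error(release_from_spikes(c(0.5, 0.1), q = 1), "sorted")
  expect_error(release_from_spikes(0.1, q = -1), "q")
})

test_that("spike-derived release can drive the metabolic unit", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  jr <- release_from_spikes(c(0.5, 0.6, 0.7), q = 0.02)
  d <- ngv_drive(2, basal = list(j_rel = p$j_rel_rest),
                 j_rel_fun = function(t) jr(t) + p$j_rel_rest)
  traj <- integrate_unit(rs, p, d, c(0, 2), dt_out = 0.01)
  expect_gt(max(traj$states[, "GLU_e"]), 2 * rs[["GLU_e"]])
})
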