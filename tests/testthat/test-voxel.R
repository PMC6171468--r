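# Voxel grid, event binning, grid simulation, normalization, NRRD export.

test_that("voxel indexing follows the half-open floor rule", {
  g <- voxel_grid(c(0, 0, 0), h = 50, dims = c(3, 2, 4))
  idx <- voxel_index(g, rbind(c(75, 10, 120), c(100, 0, 0), c(0, 0, 0)))
  expect_equal(idx[1, ], c(1L, 0L, 2L))
  expect_equal(idx[2, 1], 2L)  # internal boundary goes to the higher cell
  expect_equal(idx[3, ], c(0L, 0L, 0L))
  expect_error(voxel_index(g, rbind(c(150, 0, 0))), "outside")
  expect_error(voxel_index(g, rbind(c(-1, 0, 0))), "outside")
})

test_that("event binning is a quanta-conserving partition", {
  g <- voxel_grid(c(0, 0, 0), h = 50, dims = c(2, 2, 2))
  ev <- make_event_stream(g, rate_field = c(1, 2, 3, 4, 5, 6, 7, 8) * 3,
                          q = 40, t_span = c(0, 1), seed = 4)
  expect_true(all(diff(ev$t) >= 0))
  idx <- voxel_index(g, cbind(ev$x, ev$y, ev$z))
  expect_true(all(idx >= 0 & idx <= 1))
  vd <- assign_events(ev, g, dt_bin = 0.01, t_span = c(0, 1))
  expect_equal(sum(vd$rate) * 0.01 * g$h^3, sum(ev$q))
  # row with out-of-grid position errors and names the row
  bad <- ev
  bad$x[3] <- 1e4
  expect_error(assign_events(bad, g, 0.01), "row")
})

test_that("all-zero drive keeps every voxel at the single-unit rest", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(dims = c(2, 1, 1))
  ser <- simulate_grid(g, NULL, p, c(0, 0.2), dt_snap = 0.02,
                       species = "ATP_n", state0 = rs)
  expect_equal(dim(ser$values[["ATP_n"]]), c(11L, 2L))
  expect_identical(ser$values[["ATP_n"]][, 1], ser$values[["ATP_n"]][, 2])
  expect_lt(max(abs(ser$values[["ATP_n"]] / rs[["ATP_n"]] - 1)), 1e-6)
})

test_that("a drive confined to one voxel only perturbs that voxel", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(dims = c(2, 1, 1))
  ev <- data.frame(t = 0.05, x = 10, y = 10, z = 10, q = 5e4)
  vd <- assign_events(ev, g, dt_bin = 0.01, t_span = c(0, 0.5))
  ser <- simulate_grid(g, vd, p, c(0, 0.5), dt_snap = 0.05,
                       species = c("GLU_e", "ATP_n"), state0 = rs)
  glu <- ser$values[["GLU_e"]]
  expect_gt(max(glu[, 1]), 10 * rs[["GLU_e"]])   # driven voxel responds
  expect_lt(max(abs(glu[, 2] / rs[["GLU_e"]] - 1)), 1e-6)  # quiet voxel rests
})

test_that("grid results equal independent unit runs bit for bit", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(dims = c(2, 1, 1))
  ev <- make_event_stream(g, rate_field = c(30, 80), q = 1e4,
                          t_span = c(0, 0.3), seed = 5)
  vd <- assign_events(ev, g, dt_bin = 0.01, t_span = c(0, 0.6))
  ser <- simulate_grid(g, vd, p, c(0, 0.6), dt_snap = 0.01,
                       species = "ATP_n", state0 = rs)
  for (v in 1:2) {
    drv <- gliaflux:::voxel_drive_for(vd, v, p, c(0, 0.6))
    tr <- integrate_unit(rs, p, drv, c(0, 0.6), dt_out = 0.01)
    expect_identical(ser$values[["ATP_n"]][, v], unname(tr$states[, "ATP_n"]))
  }
})

test_that("snapshot counts follow floor(T/dt)+1 across spans", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(dims = c(1, 1, 1))
  for (case in list(c(0.2, 0.02, 11), c(0.5, 0.1, 6), c(0.3, 0.07, 5))) {
    ser <- simulate_grid(g, NULL, p, c(0, case[1]), dt_snap = case[2],
                         state0 = rs)
    expect_length(ser$times, case[3])
  }
})

test_that("normalization modes behave and round-trip", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(dims = c(1, 1, 1))
  ser <- simulate_grid(g, NULL, p, c(0, 0.1), dt_snap = 0.05,
                       species = c("ATP_n", "LAC_e"), state0 = rs)
  nf <- normalize_field(ser, "fold")
  expect_equal(max(abs(nf$values[["ATP_n"]] - 1)), 0, tolerance = 1e-6)
  back <- normalize_field(nf, "none")
  expect_identical(back$values[["ATP_n"]], ser$values[["ATP_n"]])
  mm <- normalize_field(ser, "minmax")
  expect_true(all(mm$values[["LAC_e"]] >= 0 & mm$values[["LAC_e"]] <= 1))
  ser0 <- ser
  ser0$resting[["ATP_n"]] <- 0
  expect_error(normalize_field(ser0, "fold"), "zero")
})

test_that("NRRD export writes one file per snapshot with a faithful header", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(origin = c(5, 5, 5), h = 50, dims = c(4, 4, 4))
  ser <- simulate_grid(g, NULL, p, c(0, 0.1), dt_snap = 0.05, state0 = rs)
  dir <- tempfile()
  paths <- export_snapshots(ser, dir, params = p)
  expect_length(paths, 3)
  a <- read_nrrd(paths[1])
  expect_equal(dim(a), c(4L, 4L, 4L))
  expect_equal(attr(a, "h"), 50)
  expect_equal(attr(a, "origin"), c(5, 5, 5))
  expect_equal(as.vector(a), ser$values[["ATP_n"]][1, ])
  meta <- jsonlite::fromJSON(file.path(dir, "series.json"))
  expect_equal(meta$species, "ATP_n")
  expect_length(meta$times, 3)
  # 4D mode
  p4 <- export_snapshots(ser, tempfile(), per_snapshot = FALSE)
  a4 <- read_nrrd(p4[1])
  expect_equal(dim(a4), c(4L, 4L, 4L, 3L))
})

test_that("optional ECS diffusion spreads glutamate to neighbours", {
  p <- default_params_cached()
  rs <- resting_state_cached()
  g <- voxel_grid(h = 5, dims = c(2, 1, 1))
  ev <- data.frame(t = 0.01, x = 1, y = 1, z = 1, q = 100)
  vd <- assign_events(ev, g, dt_bin = 0.01, t_span = c(0, 0.3))
  ser <- simulate_grid(g, vd, p, c(0, 0.3), dt_snap = 0.01,
                       species = "GLU_e", state0 = rs,
                       diffusion = list(D = c(GLU_e = 0.4)))
  quiet_max <- max(ser$values[["GLU_e"]][, 2])
  expect_gt(quiet_max, 1.5 * rs[["GLU_e"]])  # leakage across the face
})
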