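# GLAM absorption maps: closed-form checks, linearity, occlusion, Monte
# Carlo consistency, aggregation.

glam_k1 <- 3 / (4 * pi)  # makes a radius-1 granule emit unit power

test_that("granule power is volume-proportional", {
  expect_identical(granule_power(0), 0)
  expect_equal(granule_power(2), 8 * granule_power(1))
  expect_equal(granule_power(1, k = glam_k1), 1)
  expect_error(granule_power(-0.1), ">= 0")
})

test_that("analytic map matches the closed form directly beneath a granule", {
  pm <- patch_mesh(side = 40, n_div = 40)
  gr <- data.frame(x = 0, y = 0, z = 1, r = 1)
  mp <- absorption_map(pm, gr, mode = "analytic", k = glam_k1)[[1]]
  vi <- which(pm$vertices[, 1] == 0 & pm$vertices[, 2] == 0)
  expect_equal(mp$values[vi], 1 / (4 * pi), tolerance = 1e-12)
  expect_true(all(mp$values >= 0))
  # off-axis closed form: cos(theta)/(4 pi d^2) at (1, 0)
  vj <- which(pm$vertices[, 1] == 1 & pm$vertices[, 2] == 0)
  d2 <- 2
  expect_equal(mp$values[vj], (1 / sqrt(2)) / (4 * pi * d2), tolerance = 1e-12)
})

test_that("maps are linear in granule power and superpose exactly", {
  pm <- patch_mesh(side = 10, n_div = 10)
  gr <- data.frame(x = c(0, 2), y = c(0, -1), z = c(1, 2), r = c(1, 1.5))
  both <- absorption_map(pm, gr, mode = "analytic", k = glam_k1)[[1]]
  g1 <- absorption_map(pm, gr[1, ], mode = "analytic", k = glam_k1)[[1]]
  g2 <- absorption_map(pm, gr[2, ], mode = "analytic", k = glam_k1)[[1]]
  expect_equal(both$values, g1$values + g2$values, tolerance = 1e-15)
  dup <- absorption_map(pm, rbind(gr[1, ], gr[1, ]), mode = "analytic",
                        k = glam_k1)[[1]]
  expect_identical(dup$values, 2 * g1$values)
  half_k <- absorption_map(pm, gr[1, ], mode = "analytic", k = glam_k1 / 2)[[1]]
  expect_equal(2 * half_k$values, g1$values, tolerance = 1e-15)
})

test_that("inverse-square decay along the normal (log-log slope -2)", {
  pm <- patch_mesh(side = 60, n_div = 30)
  vi <- which(pm$vertices[, 1] == 0 & pm$vertices[, 2] == 0)
  hs <- 2^seq(0, 3, 0.5)
  Es <- vapply(hs, function(h) {
    g <- data.frame(x = 0, y = 0, z = h, r = 1)
    absorption_map(pm, g, mode = "analytic", k = glam_k1)[[1]]$values[vi]
  }, numeric(1))
  slope <- unname(coef(lm(log(Es) ~ log(hs)))[2])
  expect_lt(abs(slope - (-2)), 0.02)
})

test_that("an occluding plane casts an exact shadow", {
  pm <- patch_mesh(side = 20, n_div = 20)
  occ <- patch_mesh(side = 4, n_div = 2, z = 0.5, id = 2L)
  gr <- data.frame(x = 0, y = 0, z = 1, r = 1)
  un <- absorption_map(pm, gr, mode = "analytic", k = glam_k1)[[1]]
  oc <- absorption_map(pm, gr, mode = "analytic", occlusion = TRUE,
                       occluders = list(occ), k = glam_k1)[[1]]
  expect_true(all(oc$values <= un$values + 1e-15))
  vi <- which(pm$vertices[, 1] == 0 & pm$vertices[, 2] == 0)
  expect_identical(oc$values[vi], 0)  # directly in the shadow
  # far outside the shadow cone the map is untouched
  vo <- which(pm$vertices[, 1] == 9 & pm$vertices[, 2] == 9)
  expect_equal(oc$values[vo], un$values[vo])
})

test_that("granule on a surface is rejected; an empty set gives a null map", {
  pm <- patch_mesh(side = 4, n_div = 4)
  on_surface <- data.frame(x = 0.1, y = 0.1, z = 0, r = 0.5)
  expect_error(absorption_map(pm, on_surface, mode = "analytic"), "surface")
  none <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     r = numeric(0))
  mp <- absorption_map(pm, none, mode = "analytic")[[1]]
  expect_identical(mp$values, numeric(nrow(pm$vertices)))
})

test_that("Monte Carlo converges to the analytic map within sampling error", {
  pm <- patch_mesh(side = 10, n_div = 20)
  gr <- data.frame(x = 0, y = 0, z = 5, r = 1)
  an <- absorption_map(pm, gr, mode = "analytic", k = glam_k1)[[1]]
  mc <- absorption_map(pm, gr, mode = "montecarlo", n_photons = 2e4,
                       seed = 11, k = glam_k1)[[1]]
  interior <- which(abs(pm$vertices[, 1]) < 4.9 & abs(pm$vertices[, 2]) < 4.9)
  z <- (mc$values[interior] - an$values[interior]) /
    pmax(mc$se[interior], 1e-12)
  # per-vertex z-scores behave like noise (multiplicity-aware threshold)
  expect_gte(mean(abs(z) <= 3), 0.98)
  expect_lt(mean(abs(z)), 1.2)
  # deterministic per seed
  mc2 <- absorption_map(pm, gr, mode = "montecarlo", n_photons = 2e4,
                        seed = 11, k = glam_k1)[[1]]
  expect_identical(mc$values, mc2$values)
  expect_error(absorption_map(pm, gr, mode = "montecarlo", n_photons = 1e3),
               "seed")
})

test_that("aggregation is additive over target partitions", {
  pm1 <- patch_mesh(side = 6, n_div = 6, center_xy = c(-4, 0), id = 1L)
  pm2 <- patch_mesh(side = 6, n_div = 6, center_xy = c(4, 0), id = 2L)
  gr <- data.frame(x = 0, y = 0, z = 2, r = 1)
  maps <- absorption_map(list(pm1, pm2), gr, mode = "analytic", k = glam_k1)
  agg <- aggregate_absorption(maps, top_k = 3)
  expect_equal(nrow(agg$totals), 2)
  expect_equal(sum(agg$totals$total),
               sum(aggregate_absorption(maps[[1]])$totals$total) +
                 sum(aggregate_absorption(maps[[2]])$totals$total))
  # empty granule set -> all totals zero
  none <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                     r = numeric(0))
  empty <- absorption_map(list(pm1), none, mode = "analytic")
  expect_identical(aggregate_absorption(empty)$totals$total, 0)
  # top vertex on a flat patch under a single granule is the nearest vertex
  pm <- patch_mesh(side = 10, n_div = 10)
  g2 <- data.frame(x = 1.2, y = -0.9, z = 1.5, r = 1)
  mp <- absorption_map(pm, g2, mode = "analytic", k = glam_k1)
  top1 <- aggregate_absorption(mp, top_k = 1)$top$vertex
  foot_d <- sqrt((pm$vertices[, 1] - 1.2)^2 + (pm$vertices[, 2] + 0.9)^2)
  expect_equal(top1, which.min(foot_d))
})
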