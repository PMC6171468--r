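# Synthetic data generators: determinism, validity of generated meshes,
# planted statistical structure.

test_that("scene recipes are validated and scenes counted correctly", {
  expect_error(scene_recipe(n_axons = -1), ">= 0")
  expect_error(scene_recipe(n_axons = 0, n_boutons = 2), "axon")
  rec <- scene_recipe(n_axons = 2, n_dendrites = 0, n_boutons = 3,
                      n_spines = 0, n_astro_blobs = 1, seed = 7)
  sc <- make_neuropil(rec)
  # 2 axons + 3 boutons + 1 astrocyte object
  expect_length(sc$meshes, 6)
  expect_equal(sum(sc$manifest$class == "bouton"), 3)
  expect_equal(sum(sc$manifest$class == "astrocyte"), 1)
})

test_that("generated meshes pass the loader's validation", {
  sc <- small_scene()
  for (m in sc$meshes) {
    revalidated <- validate_mesh(m)
    expect_true(revalidated$watertight)
  }
})

test_that("same recipe and seed give byte-identical OBJ output", {
  rec <- scene_recipe(n_axons = 1, n_boutons = 1, n_spines = 0,
                      n_dendrites = 0, n_astro_blobs = 1, seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  write_scene(make_neuropil(rec)$meshes, d1)
  write_scene(make_neuropil(rec)$meshes, d2)
  for (fn in list.files(d1)) {
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
  }
  # a too-small box fails loudly
  tiny <- scene_recipe(n_axons = 2, n_boutons = 40, n_dendrites = 0,
                       n_spines = 0, n_astro_blobs = 0, box = 2, seed = 1)
  expect_error(make_neuropil(tiny), "too small")
})

test_that("granule scattering plants a recoverable polarization", {
  sc <- small_scene()
  sg <- scatter_granules(sc$meshes, 120, p_bouton = 1, seed = 9)
  expect_true(all(sg$truth$planted_class == "bouton"))
  expect_true(all(sg$granules$r >= 0.01 & sg$granules$r <= 0.04))
  tl <- nearest_element_tally(sg$granules, sc$meshes)
  expect_equal(mean(tl$assignment$object_id == sg$truth$planted_id), 1)
  # determinism
  sg2 <- scatter_granules(sc$meshes, 120, p_bouton = 1, seed = 9)
  expect_identical(sg$granules, sg2$granules)
  expect_error(scatter_granules(sc$meshes, 0), "n must be")
})

test_that("event streams have Poisson counts and in-voxel positions", {
  g <- voxel_grid(c(10, 0, 0), h = 25, dims = c(2, 2, 1))
  expect_equal(nrow(make_event_stream(g, 0, t_span = c(0, 5), seed = 1)), 0)
  rates <- c(5, 10, 20, 40)
  span <- 4
  counts <- vapply(1:20, function(s) {
    nrow(make_event_stream(g, rates, t_span = c(0, span), seed = s))
  }, numeric(1))
  lambda <- sum(rates) * span
  # mean of 20 seeds within 4 standard errors of the Poisson expectation
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 20))
  ev <- make_event_stream(g, rates, t_span = c(0, span), seed = 3)
  expect_true(all(diff(ev$t) >= 0))
  idx <- voxel_index(g, cbind(ev$x, ev$y, ev$z))
  expect_true(all(idx[, 1] >= 0 & idx[, 1] <= 1))
  # per-voxel counts concentrate where the rates are
  vox <- attr(idx, "linear")
  expect_gt(sum(vox == 4), sum(vox == 1))
})

test_that("private RNG streams never touch the global RNG state", {
  set.seed(1234)
  before <- .Random.seed
  invisible(make_neuropil(scene_recipe(seed = 5)))
  invisible(make_event_stream(voxel_grid(dims = c(2, 1, 1)), 10, seed = 8))
  expect_identical(.Random.seed, before)
})
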