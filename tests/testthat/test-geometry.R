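# Mesh container, distance kernels and morphometric operations against
# exhaustive brute-force oracles.

test_that("mesh validation names the offending elements", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_error(surface_mesh(rbind(V[1:3, ]), rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(V, rbind(c(1, 2, 3), c(1, 4, 2))), "degenerate")
  expect_error(surface_mesh(V[1:3, ], rbind(c(1, 2, 3), c(1, 2, 3))),
               "winding")
  expect_error(surface_mesh(V[1:3, ], rbind(c(1, 2, 3)), class = "soma"),
               "unknown mesh class")
  m <- icosphere(subdiv = 1)
  expect_true(m$watertight)
  expect_false(patch_mesh(2, 2)$watertight)
})

test_that("point-to-mesh distances match the no-pruning oracle", {
  m <- icosphere(c(1, 2, 3), radius = 1.5, subdiv = 2)
  set.seed(31)
  pts <- cbind(runif(25, -2, 4), runif(25, -1, 5), runif(25, 0, 6))
  fast <- dist_points_mesh(pts, m)$dist
  brute <- vapply(seq_len(nrow(pts)), function(i)
    brute_dist_point_mesh(pts[i, ], m), numeric(1))
  expect_equal(fast, brute, tolerance = 1e-12)
  # closest points actually lie on the surface
  cl <- dist_points_mesh(pts, m)$closest
  r <- sqrt(rowSums(sweep(cl, 2, c(1, 2, 3), "-")^2))
  expect_lt(max(abs(r - 1.5)), 0.04)  # chordal offset at subdiv 2
})

test_that("nearest_element_tally partitions granules with the id tie-break", {
  sc <- small_scene()
  sg <- scatter_granules(sc$meshes, 60, p_bouton = 0.7, seed = 3)
  tl <- nearest_element_tally(sg$granules, sc$meshes)
  expect_equal(sum(tl$by_class), 60)
  expect_equal(sum(tl$by_object$count), 60)
  expect_equal(tl$assignment$object_id, sg$truth$planted_id)
  # single granule close to one bouton
  one <- data.frame(x = 0, y = 0, z = 0.95, r = 0.02)
  meshes <- list(icosphere(c(0, 0, 0), 0.9, 1, class = "bouton", id = 4L),
                 icosphere(c(6, 0, 0), 1, 1, class = "axon", id = 2L))
  tl1 <- nearest_element_tally(one, meshes)
  expect_equal(tl1$assignment$class, "bouton")
  # exact tie goes to the lower object id
  tie <- data.frame(x = 0, y = 0, z = 0, r = 0.01)
  ms <- list(
    surface_mesh(rbind(c(-2, -1, -1), c(-2, 1, -1), c(-2, 0, 1)),
                 rbind(c(1, 2, 3)), class = "axon", id = 9L),
    surface_mesh(rbind(c(2, -1, -1), c(2, 1, -1), c(2, 0, 1)),
                 rbind(c(1, 2, 3)), class = "dendrite", id = 5L))
  tl2 <- nearest_element_tally(tie, ms)
  expect_equal(tl2$assignment$object_id, 5L)
  expect_error(nearest_element_tally(tie, list()), "empty")
})

test_that("contact_area matches the parallel-patch closed form and the oracle", {
  p1 <- patch_mesh(10, 10, z = 0)
  p2 <- patch_mesh(10, 10, z = 0.5, id = 2L)
  expect_equal(as.numeric(contact_area(p1, p2, 1)), 100)
  expect_equal(as.numeric(contact_area(p1, p2, 0.1)), 0)
  # sphere over plane vs exhaustive scan, several epsilons (monotone)
  sp <- icosphere(c(0, 0, 1.2), 1, 2, id = 3L)
  pl <- patch_mesh(8, 8, z = 0, id = 4L)
  prev <- -1
  for (eps in c(0.25, 0.5, 1)) {
    fast <- as.numeric(contact_area(sp, pl, eps))
    expect_equal(fast, brute_contact_area(sp, pl, eps), tolerance = 1e-12)
    expect_gte(fast, prev)
    prev <- fast
  }
  expect_error(contact_area(p1, p2, 0), "epsilon")
})

test_that("min_distance is exact, symmetric, and zero on overlap", {
  s1 <- icosphere(c(0, 0, 0), 1, 1)
  s2 <- icosphere(c(4, 0, 0), 1, 1, id = 2L)
  d12 <- min_distance(s1, s2)$distance
  expect_equal(d12, brute_min_distance(s1, s2), tolerance = 1e-12)
  expect_equal(d12, 2, tolerance = 0.02)
  expect_identical(d12, min_distance(s2, s1)$distance)
  expect_equal(min_distance(s1, icosphere(c(0.5, 0, 0), 1, 1, id = 3L))$distance, 0)
  # an edge-edge minimum (two skew boxes) against the oracle
  b1 <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  b2 <- box_mesh(c(1.4, 1.3, 0.2), c(2.4, 2.3, 1.2), id = 2L)
  expect_equal(min_distance(b1, b2)$distance, brute_min_distance(b1, b2),
               tolerance = 1e-12)
})

test_that("cross sections: cube exact, sphere analytic, plane misses", {
  bx <- box_mesh(c(-1, -1, -1), c(1, 1, 1))
  cs <- cross_section_area(bx, c(0, 0, 0), c(0, 0, 1))
  expect_identical(cs$area, 4)
  expect_identical(cs$perimeter, 8)
  s <- icosphere(subdiv = 3)
  cs2 <- cross_section_area(s, c(0, 0, 0), c(0, 0, 1))
  expect_lt(abs(cs2$area - pi) / pi, 0.01)
  expect_lt(abs(cs2$perimeter - 2 * pi) / (2 * pi), 0.01)
  # off-center cut: circle of radius sqrt(1 - 0.5^2)
  cs3 <- cross_section_area(s, c(0, 0, 0.5), c(0, 0, 1))
  expect_equal(cs3$area, pi * 0.75, tolerance = 0.02)
  expect_identical(cross_section_area(s, c(0, 0, 2), c(0, 0, 1))$area, 0)
  expect_error(cross_section_area(patch_mesh(2, 2), c(0, 0, 0), c(0, 0, 1)),
               "watertight")
})
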