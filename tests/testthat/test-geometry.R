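test_that("spec constructor validates its invariants", {
  expect_error(ttubule_spec(tubule_depth = 7), "tubule_depth")
  expect_error(ttubule_spec(radius_min = 0.3, radius_max = 0.2))
  expect_error(ttubule_spec(n_branches = 0), "n_branches")
  s <- ttubule_spec()
  expect_s3_class(s, "ttubule_spec")
  # default diameters span the measured 0.19-0.469 um range
  expect_equal(2 * s$radius_min, 0.19)
  expect_lte(2 * s$radius_max, 0.469)
  expect_equal(s$tubule_depth, 5.645)
})

test_that("generator rejects unresolvable and infeasible geometry", {
  expect_error(generate_ttubule_mesh(ttubule_spec(), 0.2), "resolve")
  # tubule wider than the box exits through the sides
  bad <- ttubule_spec(box_x = 0.6, box_y = 0.6, mouth_radius = 0.49)
  expect_error(generate_ttubule_mesh(bad, 0.09), "exits the box")
})

test_that("cylindrical variant reproduces closed-form wall area", {
  spec <- ttubule_spec(variant = "cylindrical", radius_min = 0.25,
                       radius_max = 0.25)
  mesh <- generate_ttubule_mesh(spec, 0.1)
  r <- 0.25
  lateral <- 2 * pi * r * (5.645 - r) + 2 * pi * r^2  # capsule wall + cap
  expect_equal(mesh$stats$ttubule_area, lateral, tolerance = 0.02)
  lumen <- pi * r^2 * (5.645 - r) + 2 / 3 * pi * r^3
  expect_equal(mesh$stats$compartment_volume, 2 * 2 * 5.96 - lumen,
               tolerance = 0.005)
})

test_that("default branched mesh reproduces the compartment morphometry", {
  mesh <- fx_default_mesh()
  s <- mesh$stats
  expect_equal(s$compartment_volume, 23.31, tolerance = 0.03)
  expect_equal(s$total_membrane_area, 9.00, tolerance = 0.05)
  expect_equal(s$ttubule_fraction, 0.64, tolerance = 0.03 / 0.64)
  expect_equal(s$external_area, 3.25, tolerance = 0.03)
  expect_equal(s$tubule_depth, 5.645)
})

test_that("label partition covers the boundary exactly", {
  mesh <- fx_default_mesh()
  s <- mesh$stats
  expect_equal(s$ttubule_area + s$external_area, s$total_membrane_area)
  expect_equal(s$total_membrane_area + s$reflective_area,
               sum(mesh$facet_area))
  expect_true(all(mesh$facet_label %in%
                    c("external_membrane", "ttubule_membrane",
                      "reflective")))
  # watertightness: the boundary facets close every tetrahedron face
  # that is not shared -- verified by construction; check counts agree
  expect_gt(nrow(mesh$facets), 0)
  # compartment fits inside the box
  expect_lt(s$compartment_volume, 2 * 2 * 5.96)
})

test_that("unit-box stats: volume and area of a cube-like box mesh", {
  # a box-only domain: cylindrical spec with the tubule shrunk so far
  # that carving it changes almost nothing is not available; instead
  # verify on the grid generator directly via a tiny tubule-free check
  # using stats of a read-back synthetic box built from a small mesh
  spec <- ttubule_spec(box_x = 1, box_y = 1, box_depth = 1.5,
                       tubule_depth = 1.2, variant = "cylindrical",
                       radius_min = 0.18, radius_max = 0.18,
                       mouth_center = c(0.5, 0.5))
  mesh <- generate_ttubule_mesh(spec, 0.1)
  expect_equal(sum(signif(mesh$facet_area, 12)) -
                 mesh$stats$total_membrane_area,
               mesh$stats$reflective_area, tolerance = 1e-9)
  # box faces: bottom + 4 sides are reflective
  expect_equal(mesh$stats$reflective_area, 1 * 1 + 4 * 1 * 1.5,
               tolerance = 1e-6)
})

test_that("geometry stats converge under mesh refinement", {
  spec <- ttubule_spec(box_x = 1, box_y = 1, box_depth = 1.5,
                       tubule_depth = 1.2, variant = "cylindrical",
                       radius_min = 0.18, radius_max = 0.18,
                       mouth_center = c(0.5, 0.5))
  s1 <- generate_ttubule_mesh(spec, 0.09)$stats
  s2 <- generate_ttubule_mesh(spec, 0.045)$stats
  expect_equal(s1$compartment_volume, s2$compartment_volume,
               tolerance = 0.02)
  expect_equal(s1$ttubule_area, s2$ttubule_area, tolerance = 0.02)
  expect_equal(s1$total_membrane_area, s2$total_membrane_area,
               tolerance = 0.02)
})

test_that("identical spec and seed give bit-identical meshes", {
  spec <- fx_test_spec()
  m1 <- generate_ttubule_mesh(spec, 0.13)
  m2 <- generate_ttubule_mesh(spec, 0.13)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$facet_label, m2$facet_label)
  # a different seed moves the skeleton
  m3 <- generate_ttubule_mesh(ttubule_spec(radius_min = 0.14,
                                           radius_max = 0.20,
                                           branch_radius = 0.16,
                                           seed = 7L), 0.13)
  expect_false(isTRUE(all.equal(m1$stats$ttubule_area,
                                m3$stats$ttubule_area, tolerance = 1e-9)))
})

test_that("all elements have positive volume and facets positive area", {
  mesh <- fx_test_mesh()
  vols <- diff(range(mesh$vertices[, 3]))  # sanity on coordinates
  expect_gt(vols, 5)
  expect_true(all(mesh$facet_area > 0))
  st <- compute_geometry_stats(mesh)      # errors on inverted elements
  expect_gt(st$compartment_volume, 0)
})

test_that("membrane distance field: zeros on membrane, exact analytics", {
  spec <- ttubule_spec(box_x = 1, box_y = 1, box_depth = 1.5,
                       tubule_depth = 1.2, variant = "cylindrical",
                       radius_min = 0.18, radius_max = 0.18,
                       mouth_center = c(0.5, 0.5))
  mesh <- generate_ttubule_mesh(spec, 0.1)
  d <- distance_to_membrane_field(mesh)
  # vertices on membrane facets are at distance zero
  memb_v <- unique(as.vector(
    mesh$facets[mesh$facet_label != "reflective", ]))
  expect_lt(max(d[memb_v]), 1e-12)
  # a vertex radially outside the tubule wall: distance ~ radial gap
  # (up to facet chord error) or the distance to the top face
  v <- mesh$vertices
  rad <- sqrt((v[, 1] - 0.5)^2 + (v[, 2] - 0.5)^2)
  pick <- which(abs(rad - 0.38) < 0.03 & abs(v[, 3] - 0.6) < 0.05)
  expect_gt(length(pick), 0)
  expected <- pmin(rad[pick] - 0.18, v[pick, 3])
  expect_equal(d[pick], expected, tolerance = 0.02)
  # deep corner vertex: closest membrane is the top face or tubule cap
  corner <- which.min(-(v[, 3]))  # deepest vertex set
  expect_true(all(d <= pmax(v[, 3], 0) + 1e-9))
})
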