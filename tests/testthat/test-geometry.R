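test_that("voxel meshing: cube splits, shared faces, exact volume", {
  box1 <- box_spec(10, 10, 10, 10)
  m1 <- voxel_to_tets(array(TRUE, c(1, 1, 1)), box1)
  expect_equal(nrow(m1$nodes), 8L)
  expect_equal(nrow(m1$tets), 6L)
  expect_equal(m1$V_omega, 1000)

  box2 <- box_spec(20, 10, 10, 10)
  m2 <- voxel_to_tets(array(TRUE, c(2, 1, 1)), box2)
  expect_equal(nrow(m2$nodes), 12L)   # shared face contributes 4 nodes once
  expect_equal(nrow(m2$tets), 12L)
  expect_equal(m2$V_omega, 2000)
  expect_true(all(m2$vol > 0))

  ## volume conservation on an irregular mask
  mask <- array(FALSE, c(3, 3, 3))
  mask[1, , ] <- TRUE; mask[, 2, ] <- TRUE
  box3 <- box_spec(30, 30, 30, 10)
  m3 <- voxel_to_tets(largest_component(mask)$mask, box3)
  expect_equal(m3$V_omega, sum(largest_component(mask)$mask) * 1000,
               tolerance = 1e-12)
})

test_that("voxel meshing rejects non-face-connected masks", {
  mask <- array(FALSE, c(2, 2, 1))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 1] <- TRUE          # corner-connected checkerboard
  expect_error(voxel_to_tets(mask, box_spec(20, 20, 10, 10)),
               "not face-connected")
  expect_error(voxel_to_tets(array(FALSE, c(2, 2, 1)),
                             box_spec(20, 20, 10, 10)), "empty")
})

test_that("box spec validates its invariants", {
  expect_error(box_spec(100, 100, 100, 33), "integer multiple")
  expect_error(box_spec(-1, 100, 100, 10), "positive")
  expect_error(box_spec(100, 100, 100, 0), "positive")
})

test_that("structured generator hits its porosity target and validates", {
  expect_error(structured_spec(diameter = 600, spacing = 600),
               "overlap fully")
  mesh <- rom_fixture()$mesh
  expect_equal(mesh$metadata$porosity, 0.541, tolerance = 0.03 / 0.541)
  ## vanishing strands: the mesh fills the whole box
  thin <- generate_structured(box_spec(300, 300, 300, 50),
                              structured_spec(diameter = 1e-6, spacing = 300))
  expect_equal(thin$metadata$porosity, 1.0)
  expect_equal(thin$V_omega, 300^3, tolerance = 1e-12)
})

test_that("foamed generator is seed-deterministic and hits porosity", {
  box <- box_spec(400, 400, 400, 50)
  a <- generate_foamed(box, foamed_spec(seed = 11))
  b <- generate_foamed(box, foamed_spec(seed = 11))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_identical(a$facet_tag, b$facet_tag)

  big <- foam_fixture()$mesh
  expect_equal(big$metadata$porosity, 0.523, tolerance = 0.03 / 0.523)
  expect_identical(big$metadata$seed, 42L)

  expect_error(
    generate_foamed(box, foamed_spec(median_radius = 8, target_porosity = 0.9,
                                     seed = 1), max_spheres = 20L),
    "unreachable")
})

test_that("boundary tagging partitions the surface and books areas", {
  mesh <- rom_fixture()$mesh
  expect_false(anyNA(mesh$facet_tag))
  ar <- boundary_areas(mesh)
  expect_equal(sum(ar), sum(facet_areas(mesh)), tolerance = 1e-10)
  expect_true(all(ar > 0))

  ## full box with no solid: only inlet/outlet planes, solid empty
  box <- box_spec(100, 100, 100, 25)
  full <- tag_boundaries(voxel_to_tets(array(TRUE, box$n), box), box)
  ab <- boundary_areas(full)
  expect_equal(unname(ab["solid"]), 0)
  expect_equal(unname(ab["inlet"]), 3 * 100^2, tolerance = 1e-12)
  expect_equal(unname(ab["outlet"]), 3 * 100^2, tolerance = 1e-12)
})

test_that("an interior pore never touching the walls cannot host a flow", {
  ## sphere of fluid strictly inside the box: boundary is all solid
  box <- box_spec(200, 200, 200, 25)
  cc <- (seq_len(8) - 0.5) * 25   # voxel centres
  d2 <- outer(outer((cc - 100)^2, (cc - 100)^2, `+`), (cc - 100)^2, `+`)
  mask <- d2 < 60^2
  mesh <- tag_boundaries(voxel_to_tets(mask, box), box)
  expect_equal(sum(mesh$facet_tag != 3L), 0L)
  expect_error(solve_potential(mesh, "x"), "singular")
})
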