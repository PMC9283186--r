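test_that("potential in an empty box is the exact linear drop", {
  box <- box_spec(200, 100, 100, 25)
  mesh <- tag_boundaries(voxel_to_tets(array(TRUE, box$n), box), box)
  phi <- solve_potential(mesh, "x")
  expect_lt(max(abs(phi - (1 - mesh$nodes[, 1] / 200))), 1e-8)
  expect_gte(min(phi), -1e-10)
  expect_lte(max(phi), 1 + 1e-10)

  v <- velocity_from_potential(mesh, phi)
  expect_equal(v[, 1], rep(1 / 200, nrow(v)), tolerance = 1e-10)
  expect_lt(max(abs(v[, 2:3])), 1e-12)

  ## constant potential has zero velocity
  v0 <- velocity_from_potential(mesh, rep(0.7, nrow(mesh$nodes)))
  expect_lt(max(abs(v0)), 1e-12)
})

test_that("potential respects bounds and flux balance on a constriction", {
  ## duct with a mid-plane constriction to a single voxel column
  box <- box_spec(200, 100, 100, 25)
  mask <- array(TRUE, box$n)
  mask[4:5, , ] <- FALSE
  mask[4:5, 2:3, 2:3] <- TRUE
  mesh <- tag_boundaries(voxel_to_tets(mask, box), box,
                         inlet = "xmin", outlet = "xmax")
  phi <- solve_potential(mesh, "x")
  expect_gte(min(phi), -1e-10)
  expect_lte(max(phi), 1 + 1e-10)
  fl <- potential_fluxes(mesh, phi, "x")
  expect_lt(fl$imbalance, 1e-8)
  expect_true(fl$inflow * fl$outflow < 0)   # opposite signs
})

test_that("nodal gradient averaging recovers smooth gradients", {
  box <- box_spec(200, 200, 200, 25)
  mesh <- voxel_to_tets(array(TRUE, box$n), box)
  ctr <- c(100, 100, 100)
  phi <- rowSums((mesh$nodes - rep(ctr, each = nrow(mesh$nodes)))^2) / 1e4
  v <- velocity_from_potential(mesh, phi)
  exact <- -2 * (mesh$nodes - rep(ctr, each = nrow(mesh$nodes))) / 1e4
  interior <- rowSums(mesh$nodes > 0 & mesh$nodes < 200) == 3
  expect_lt(max(abs(v[interior, ] - exact[interior, ])), 0.3 * 25 / 1e4 * 2)
})

test_that("normalization yields unit mean speed and is idempotent", {
  box <- box_spec(100, 100, 100, 25)
  mesh <- voxel_to_tets(array(TRUE, box$n), box)
  n <- nrow(mesh$nodes)
  const <- matrix(rep(c(3, 0, 4), each = n), n)  # |v| = 5 everywhere
  nf <- normalize_field(const, mesh)
  expect_equal(nf$constant, 5, tolerance = 1e-12)
  expect_equal(nf$field[1, ], c(3, 0, 4) / 5, tolerance = 1e-12)
  again <- normalize_field(nf$field, mesh)
  expect_equal(again$constant, 1, tolerance = 1e-10)
  expect_equal(again$field, nf$field, tolerance = 1e-12)

  set.seed(99)
  arb <- matrix(rnorm(3 * n), n)
  fs <- fe_structure(tag_boundaries(mesh, box))
  nrm <- normalize_field(arb, mesh, fs = fs)
  ve <- (nrm$field[mesh$tets[, 1], ] + nrm$field[mesh$tets[, 2], ] +
         nrm$field[mesh$tets[, 3], ] + nrm$field[mesh$tets[, 4], ]) / 4
  mean_speed <- sum(mesh$vol * sqrt(rowSums(ve^2))) / sum(mesh$vol)
  expect_equal(mean_speed, 1, tolerance = 1e-10)

  expect_error(normalize_field(matrix(0, n, 3), mesh), "zero")
})

test_that("velocity combination follows the direction-cosine rule", {
  f <- rom_fixture()
  cmb <- combine_velocity(f$vb, 2, 45, 45)
  expect_equal(cmb$coefficients, c(0.5, 0.5, sqrt(2) / 2), tolerance = 1e-14)
  expect_equal(cmb$field,
               2 * (0.5 * f$vb$vx + 0.5 * f$vb$vy + sqrt(2) / 2 * f$vb$vz),
               tolerance = 1e-14)

  expect_equal(combine_velocity(f$vb, 0, 30, 60)$field,
               0 * f$vb$vx, tolerance = 0)

  ## axis-aligned limit (warns: outside modelled angle range)
  expect_warning(ax <- combine_velocity(f$vb, 3, 90, 0), "outside")
  expect_equal(ax$field, 3 * f$vb$vx, tolerance = 1e-14)

  expect_error(combine_velocity(f$vb, -1, 45, 45), "non-negative")

  ## unit coefficient norm for arbitrary angles; homogeneity in v
  for (g in c(10, 35, 80)) for (b in c(10, 55, 80)) {
    co <- combine_velocity(f$vb, 1, g, b)$coefficients
    expect_equal(sum(co^2), 1, tolerance = 1e-14)
  }
  expect_equal(combine_velocity(f$vb, 7, 20, 70)$field,
               7 * combine_velocity(f$vb, 1, 20, 70)$field,
               tolerance = 1e-14)
})

test_that("each basis field conserves mass through the domain", {
  f <- rom_fixture()
  for (ax in c("x", "y", "z")) {
    phi <- solve_potential(f$mesh, ax, fs = f$fs)
    fl <- potential_fluxes(f$mesh, phi, ax, fs = f$fs)
    expect_lt(fl$imbalance, 1e-8)
  }
})
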