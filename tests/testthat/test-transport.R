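test_that("Stokes-Einstein diffusivity evaluates the canonical values", {
  ## hand evaluation: 1.38e-23 * 310.15 / (6 pi eta 114e-12)
  expect_equal(stokes_einstein(1e-3)$m2_s, 1.99179e-9,
               tolerance = 1e-5)
  expect_equal(stokes_einstein(7e-4)$m2_s, 2.84541e-9,
               tolerance = 1e-5)
  ## inverse proportionality in eta
  expect_equal(stokes_einstein(2e-3)$m2_s, stokes_einstein(1e-3)$m2_s / 2,
               tolerance = 1e-14)
  expect_equal(stokes_einstein(1e-3)$um2_s, stokes_einstein(1e-3)$m2_s * 1e12)
  expect_error(stokes_einstein(0), "positive")
  expect_error(stokes_einstein(-1e-3), "positive")
})

test_that("concentration-dependent diffusivity follows the crowding law", {
  D <- stokes_einstein(1e-3)$um2_s
  c <- seq(0, 1, 0.25)
  expect_equal(diffusivity(c, 0, 1e-3), rep(D, 5), tolerance = 1e-14)
  expect_equal(diffusivity(1, 1, 1e-3), D / 10, tolerance = 1e-14)
  expect_equal(diffusivity(0, 0.7, 1e-3), D, tolerance = 1e-14)
  expect_error(diffusivity(c(0, NaN), 0.5, 1e-3), "non-finite")
})

test_that("single-element assembly matches an independent dense oracle", {
  mesh <- single_tet_mesh()
  fs <- fe_structure(mesh)
  nu <- 3.7
  vel <- c(1.5, -0.5, 2)
  r_eff <- 2.25

  sys <- assemble_system(fs, nu, rbind(vel), r_eff)
  K <- as.matrix(sys$K)

  ## oracle: solve for the P1 coefficients directly
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4))
  M <- cbind(1, P)
  coef <- solve(M, diag(4))          # column i: coefficients of N_i
  G <- coef[2:4, ]                   # 3 x 4 gradients
  V <- det(cbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])) / 6
  K_ref <- nu * V * t(G) %*% G
  for (i in 1:4) for (j in 1:4)
    K_ref[i, j] <- K_ref[i, j] + V / 4 * sum(vel * G[, j])
  ## lumped Robin mass: each facet puts area/3 on its corner diagonals
  ar <- facet_areas(mesh)
  f_ref <- numeric(4)
  for (k in seq_len(nrow(mesh$facets))) for (v in mesh$facets[k, ]) {
    K_ref[v, v] <- K_ref[v, v] + r_eff * ar[k] / 3
    f_ref[v] <- f_ref[v] + r_eff * ar[k] / 3
  }
  expect_equal(K, K_ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sys$f, f_ref, tolerance = 1e-12)

  ## no inlet, no advection: c = 1 satisfies the discrete system exactly
  sys1 <- assemble_system(fs, nu, NULL, r_eff)
  expect_equal(as.vector(Matrix::solve(sys1$K, sys1$f)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("zero release rate gives the identically zero solution", {
  f <- rom_fixture()
  sol <- quiet_solve(f$mesh, mid_mu(r = 0), f$vb, fs = f$fs)
  expect_equal(max(abs(sol$c)), 0)
  expect_identical(sol$converged, TRUE)
})

test_that("linear problems converge on the second Picard iteration", {
  f <- rom_fixture()
  sol <- quiet_solve(f$mesh, mid_mu(alpha = 0), f$vb, fs = f$fs)
  expect_identical(sol$iterations, 2L)
  expect_lt(sol$residuals[2], 1e-13)
})

test_that("solver matches the 1-D duct closed form at O(h^2)", {
  v <- 20; eta <- 1e-3; r <- 1.25
  nu <- stokes_einstein(eta)$um2_s
  settings <- solver_settings()
  errs <- vapply(c(8, 16), function(nx) {
    mesh <- duct_fixture(nx)
    fs <- fe_structure(mesh)
    vb <- velocity_basis(mesh, fs = fs)
    mu <- parameter_point(v, 90, 0, 0, eta, r)
    sol <- suppressWarnings(quiet_solve(mesh, mu, vb, settings, fs = fs))
    max(abs(sol$c - duct_oracle(mesh$nodes[, 1], v, nu,
                                r * settings$r_scale, 200)))
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 3)      # better than first order
  expect_lt(errs[2], 2e-3)
})

test_that("concentration is monotone in release rate and velocity", {
  f <- rom_fixture()
  cr <- lapply(c(0.5, 1.25, 2), function(r)
    quiet_solve(f$mesh, mid_mu(r = r), f$vb, fs = f$fs)$c)
  expect_true(all(cr[[2]] >= cr[[1]] - 1e-10))
  expect_true(all(cr[[3]] >= cr[[2]] - 1e-10))

  cv <- lapply(c(1, 30, 60), function(v)
    quiet_solve(f$mesh, mid_mu(v = v), f$vb, fs = f$fs)$c)
  expect_true(all(cv[[2]] <= cv[[1]] + 1e-10))
  expect_true(all(cv[[3]] <= cv[[2]] + 1e-10))
})

test_that("large release rates drive the wall concentration to saturation", {
  f <- rom_fixture()
  wall <- setdiff(boundary_nodes(f$mesh, "solid"),
                  boundary_nodes(f$mesh, "inlet"))
  mins <- vapply(c(1, 10, 100, 1000), function(sc)
    min(quiet_solve(f$mesh, mid_mu(), f$vb,
                    solver_settings(r_scale = sc), fs = f$fs)$c[wall]),
    numeric(1))
  expect_true(all(diff(mins) > 0))
  expect_gt(mins[4], 0.9)
})

test_that("a converged solution is a Picard fixed point", {
  f <- rom_fixture()
  mu <- mid_mu(alpha = 0.8)
  sol <- quiet_solve(f$mesh, mu, f$vb, fs = f$fs)
  D <- stokes_einstein(mu[["eta"]])$um2_s
  nu_e <- D * 10^(-mu[["alpha"]] *
    rowMeans(matrix(sol$c[f$mesh$tets], ncol = 4)))
  adv <- combine_velocity(f$vb, mu[["v"]], mu[["gamma"]], mu[["beta"]])
  adv_e <- (adv$field[f$mesh$tets[, 1], ] + adv$field[f$mesh$tets[, 2], ] +
            adv$field[f$mesh$tets[, 3], ] + adv$field[f$mesh$tets[, 4], ]) / 4
  sys <- assemble_system(f$fs, nu_e, adv_e, mu[["r"]] * 10)
  c_next <- as.vector(Matrix::solve(sys$K, sys$f))
  expect_lt(sqrt(sum((c_next - sol$c)^2)) / sqrt(sum(c_next^2)), 1e-8)
})

test_that("the iteration cap raises an informative error", {
  f <- rom_fixture()
  expect_error(
    picard_solve(f$mesh, mid_mu(alpha = 0.9), f$vb,
                 solver_settings(max_iter = 2L), fs = f$fs),
    "did not converge")
})
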