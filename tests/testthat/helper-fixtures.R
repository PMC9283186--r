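# Shared fixtures, memoized per test run. The ROM benchmark fixture is a
# 600^3 um structured (woodpile) domain at h = 50 um (~1.3k nodes), sized
# for the one-CPU test budget; the foamed companion uses the same box.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

rom_fixture <- function() fixture("rom", function() {
  mesh <- generate_structured(box_spec(600, 600, 600, 50))
  fs <- fe_structure(mesh)
  vb <- velocity_basis(mesh, fs = fs)
  list(mesh = mesh, fs = fs, vb = vb)
})

foam_fixture <- function() fixture("foam", function() {
  mesh <- generate_foamed(box_spec(600, 600, 600, 50), foamed_spec(seed = 42))
  fs <- fe_structure(mesh)
  vb <- velocity_basis(mesh, fs = fs)
  list(mesh = mesh, fs = fs, vb = vb)
})

## 64-snapshot corner training set on the ROM fixture
rom_snapshots64 <- function() fixture("snaps64", function() {
  f <- rom_fixture()
  suppressMessages(build_snapshots(f$mesh, corner_sampling(), f$vb, fs = f$fs))
})

## 729-snapshot 3-level grid training set (the expensive enrichment)
rom_snapshots729 <- function() fixture("snaps729", function() {
  f <- rom_fixture()
  suppressMessages(build_snapshots(f$mesh, grid_sampling(default_ranges(), 3),
                                   f$vb, fs = f$fs))
})

## axis-aligned duct with inlet at x = 0, Robin wall at x = L, zero-flux
## sides: the 1-D two-point boundary-value oracle geometry
duct_fixture <- function(nx, L = 200) {
  h <- L / nx
  box <- box_spec(L, 2 * h, 2 * h, h)
  mesh <- voxel_to_tets(array(TRUE, box$n), box)
  tag_boundaries(mesh, box, inlet = "xmin",
                 outlet = c("ymin", "ymax", "zmin", "zmax"))
}

## closed-form solution of -nu c'' + v c' = 0, c(0)=0, -nu c'(L) = r(c(L)-1)
duct_oracle <- function(x, v, nu, r, L) {
  P <- v * L / nu
  A <- r / (r * (exp(P) - 1) + v * exp(P))
  A * (exp(v * x / nu) - 1)
}

## single general tetrahedron with all-solid boundary (hand-assembly oracle)
single_tet_mesh <- function() {
  m <- tet_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 4)),
                matrix(1:4, 1))
  m$facet_tag <- rep(3L, nrow(m$facets))
  m
}

mid_mu <- function(...) {
  p <- list(v = 30, gamma = 45, beta = 45, alpha = 0.5, eta = 1e-3, r = 1.25)
  do.call(parameter_point, utils::modifyList(p, list(...)))
}

quiet_solve <- function(...) suppressMessages(picard_solve(...))
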