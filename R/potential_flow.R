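## Potential-flow velocity basis. Each directional field solves Laplace's
## equation with unit potential drop across the axis' box faces and
## natural (impermeable) conditions elsewhere; the advection field for a
## parameter point is the normalized combination
## v (sin g cos b v_x + sin g sin b v_y + cos g v_z).

#' Solve Laplace's equation for a directional flow potential
#'
#' P1 Galerkin solve of `-div(grad phi) = 0` with `phi = 1` on the axis'
#' minimum box face, `phi = 0` on its maximum face, and zero normal flux
#' on every other boundary facet (including the scaffold surface).
#'
#' @param mesh a tagged `tet_mesh`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param fs optional precomputed [fe_structure()] (only its geometry is
#'   used; Dirichlet data is rebuilt from the box planes).
#' @return nodal potential vector in `[0, 1]` (up to FE tolerance).
#' @export
solve_potential <- function(mesh, axis = c("x", "y", "z"), fs = NULL) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  box <- mesh$box
  if (is.null(box)) stop("mesh carries no box_spec; potential BCs need box planes")
  tol <- 1e-6 * (mesh$h %||% 1)
  on_min <- abs(mesh$nodes[, ax]) < tol
  on_max <- abs(mesh$nodes[, ax] - box$L[ax]) < tol
  ## restrict to nodes actually on the boundary surface
  bnodes <- sort(unique(as.vector(mesh$facets)))
  on_min[-bnodes] <- FALSE
  on_max[-bnodes] <- FALSE
  if (!any(on_min) || !any(on_max))
    stop("no boundary facets on the ", axis, " box planes: system is singular")

  if (is.null(fs)) fs <- fe_structure(mesh, require_tags = FALSE)
  vals <- fs$Kd                                  # unit diffusivity
  I <- fs$I16; J <- fs$J16; V <- as.vector(vals)

  dir <- which(on_min | on_max)
  g <- numeric(fs$n)
  g[on_min] <- 1
  ## lift the Dirichlet data: f <- -K g on free nodes
  K0 <- Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(fs$n, fs$n))
  f <- -as.vector(K0 %*% g)
  isdir <- logical(fs$n); isdir[dir] <- TRUE
  keep <- !(isdir[I] | isdir[J])
  I <- c(I[keep], dir); J <- c(J[keep], dir)
  V <- c(V[keep], rep(1, length(dir)))
  f[dir] <- g[dir]
  K <- Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(fs$n, fs$n))
  phi <- as.vector(Matrix::solve(K, f))
  phi
}

#' Discrete boundary fluxes of a flow potential
#'
#' Consistent (residual-based) fluxes through the Dirichlet planes of a
#' potential solve: the Galerkin residual `K phi` vanishes at free nodes,
#' so its sums over the inlet- and outlet-plane node sets are the discrete
#' boundary fluxes, and they balance to round-off (weak incompressibility
#' of the potential flow).
#'
#' @param mesh a `tet_mesh`.
#' @param phi nodal potential from [solve_potential()].
#' @param axis the axis the potential was solved along.
#' @param fs optional precomputed [fe_structure()].
#' @return list with `inflow`, `outflow` (signed residual sums) and
#'   `imbalance` (their sum relative to the inflow magnitude).
#' @export
potential_fluxes <- function(mesh, phi, axis = c("x", "y", "z"), fs = NULL) {
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  if (is.null(fs)) fs <- fe_structure(mesh, require_tags = FALSE)
  tol <- 1e-6 * (mesh$h %||% 1)
  on_min <- abs(mesh$nodes[, ax]) < tol
  on_max <- abs(mesh$nodes[, ax] - mesh$box$L[ax]) < tol
  K0 <- Matrix::sparseMatrix(i = fs$I16, j = fs$J16, x = as.vector(fs$Kd),
                             dims = c(fs$n, fs$n))
  res <- as.vector(K0 %*% phi)
  inflow <- sum(res[on_min])
  outflow <- sum(res[on_max])
  list(inflow = inflow, outflow = outflow,
       imbalance = abs(inflow + outflow) / max(abs(inflow), .Machine$double.eps))
}

#' Nodal velocity from a scalar potential
#'
#' Element gradients of the P1 potential are constant; the nodal field is
#' their volume-weighted average over the elements sharing each node, and
#' the velocity is the negative gradient.
#'
#' @param mesh a `tet_mesh`.
#' @param phi nodal potential.
#' @param fs optional precomputed [fe_structure()].
#' @return n x 3 matrix of nodal velocities.
#' @export
velocity_from_potential <- function(mesh, phi, fs = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh, require_tags = FALSE)
  ge <- matrix(0, fs$m, 3L)
  for (i in 1:4) ge <- ge + fs$grad[[i]] * phi[fs$tets[, i]]
  v_e <- -ge
  acc <- matrix(0, fs$n, 3L)
  w <- numeric(fs$n)
  for (i in 1:4) {
    idx <- fs$tets[, i]
    for (d in 1:3) {
      s <- tapply(fs$vol * v_e[, d], idx, sum)
      at <- as.integer(names(s))
      acc[at, d] <- acc[at, d] + as.vector(s)
    }
    sw <- tapply(fs$vol, idx, sum)
    at <- as.integer(names(sw))
    w[at] <- w[at] + as.vector(sw)
  }
  acc / w
}

#' Normalize a nodal vector field to unit volume-averaged speed
#'
#' Divides by the mean interstitial speed `(1/V) int |v| dV` computed with
#' one-point element quadrature, so the velocity-module parameter is the
#' mean speed in the pore space.
#'
#' @param field n x 3 nodal vector field.
#' @param mesh the `tet_mesh` the field lives on.
#' @param fs optional precomputed [fe_structure()].
#' @return list with `field` (normalized) and `constant` (the mean speed
#'   divided out).
#' @export
normalize_field <- function(field, mesh, fs = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh, require_tags = FALSE)
  v_e <- elem_mean_vec(fs, field)
  mean_speed <- sum(fs$vol * sqrt(rowSums(v_e^2))) / sum(fs$vol)
  if (mean_speed <= 0) stop("cannot normalize an identically zero field")
  list(field = field / mean_speed, constant = mean_speed)
}

#' Compute the three-direction potential-flow velocity basis
#'
#' Solves the flow potential along each axis, differentiates, and
#' normalizes each directional field to unit mean speed.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param fs optional precomputed [fe_structure()].
#' @return object of class `velocity_basis` with fields `vx`, `vy`, `vz`
#'   (n x 3 each), `constants`, and `fingerprint` of the mesh.
#' @export
velocity_basis <- function(mesh, fs = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh)
  out <- lapply(c("x", "y", "z"), function(ax) {
    phi <- solve_potential(mesh, ax, fs = fs)
    normalize_field(velocity_from_potential(mesh, phi, fs = fs), mesh, fs = fs)
  })
  structure(list(vx = out[[1]]$field, vy = out[[2]]$field, vz = out[[3]]$field,
                 constants = vapply(out, `[[`, numeric(1), "constant"),
                 fingerprint = mesh_fingerprint(mesh)),
            class = "velocity_basis")
}

#' Parametrized advection field
#'
#' Combines the normalized directional fields with inflow direction
#' angles: `v (sin g cos b vx + sin g sin b vy + cos g vz)`, with `gamma`
#' and `beta` in degrees. The direction cosines have unit Euclidean norm
#' for any angles.
#'
#' @param basis a [velocity_basis()].
#' @param v velocity module (um/s), >= 0.
#' @param gamma,beta inflow angles in degrees; a warning (not an error) is
#'   issued outside the modelled range `[10, 80]`.
#' @return object of class `advection_field`: n x 3 matrix `field` plus
#'   the parameters used.
#' @export
combine_velocity <- function(basis, v, gamma, beta) {
  if (v < 0) stop("velocity module v must be non-negative")
  if (gamma < 10 || gamma > 80 || beta < 10 || beta > 80)
    warning("inflow angles outside the modelled range [10, 80] degrees")
  g <- gamma * pi / 180
  b <- beta * pi / 180
  co <- c(sin(g) * cos(b), sin(g) * sin(b), cos(g))
  field <- v * (co[1] * basis$vx + co[2] * basis$vy + co[3] * basis$vz)
  structure(list(field = field, v = v, gamma = gamma, beta = beta,
                 coefficients = co),
            class = "advection_field")
}
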