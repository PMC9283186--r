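## P1 Galerkin core on linear tetrahedra. Per-element shape-function
## gradients are constant, so stiffness/advection/SUPG element matrices
## reduce to closed-form products that are precomputed once per mesh
## (fe_structure) and rescaled per assembly (diffusivity changes along the
## Picard iteration; the advection field changes per parameter point).

vec_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Precompute element geometry and assembly indexing for a mesh
#'
#' Computes constant P1 shape-function gradients, element volumes, the
#' 16-entry stiffness stencil per element, sparse triplet index vectors,
#' and the Robin boundary (solid-interface) facet data. The result is
#' reused across assemblies for the same mesh.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param robin_lumped use the lumped (diagonal) P1 mass matrix for the
#'   Robin boundary term (default). Lumping preserves the O(h^2)
#'   convergence order and keeps coarse-mesh solutions inside [0, 1] in
#'   regimes where the consistent mass overshoots slightly.
#' @param require_tags demand a tagged boundary (needed for transport
#'   assembly; pure geometry post-processing may pass `FALSE`).
#' @return object of class `fe_structure`.
#' @export
fe_structure <- function(mesh, robin_lumped = TRUE, require_tags = TRUE) {
  untagged <- anyNA(mesh$facet_tag)
  if (untagged && require_tags)
    stop("mesh boundary is untagged; run tag_boundaries()")
  tets <- mesh$tets
  m <- nrow(tets)
  n <- nrow(mesh$nodes)
  vol <- mesh$vol
  if (any(vol <= 0)) stop("element with non-positive volume")

  p1 <- mesh$nodes[tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- mesh$nodes[tets[, 4], , drop = FALSE] - p1
  det6V <- 6 * vol
  grad <- vector("list", 4L)              # grad[[i]]: m x 3 gradient of N_i
  grad[[2]] <- vec_cross(e2, e3) / det6V
  grad[[3]] <- vec_cross(e3, e1) / det6V
  grad[[4]] <- vec_cross(e1, e2) / det6V
  grad[[1]] <- -(grad[[2]] + grad[[3]] + grad[[4]])

  ## unit-diffusivity stiffness stencil: column p = (i,j) -> V * gi . gj
  Kd <- matrix(0, m, 16L)
  I16 <- matrix(0L, m, 16L)
  J16 <- matrix(0L, m, 16L)
  for (i in 1:4) for (j in 1:4) {
    p <- (i - 1L) * 4L + j
    Kd[, p] <- vol * rowSums(grad[[i]] * grad[[j]])
    I16[, p] <- tets[, i]
    J16[, p] <- tets[, j]
  }

  ## Robin (solid) facets
  sol <- if (untagged) rep(FALSE, nrow(mesh$facets))
         else mesh$facet_tag == SOLID
  rfac <- mesh$facets[sol, , drop = FALSE]
  rarea <- facet_areas(mesh)[sol]
  nr <- nrow(rfac)
  Ir <- matrix(0L, nr, 9L); Jr <- matrix(0L, nr, 9L); Mr <- matrix(0, nr, 9L)
  if (nr > 0) {
    for (i in 1:3) for (j in 1:3) {
      q <- (i - 1L) * 3L + j
      Ir[, q] <- rfac[, i]
      Jr[, q] <- rfac[, j]
      Mr[, q] <- if (robin_lumped) {
        if (i == j) rarea / 3 else 0           # lumped triangle mass
      } else {
        rarea * (1 + (i == j)) / 12            # consistent triangle mass
      }
    }
  }

  structure(list(
    n = n, m = m, tets = tets, vol = vol, grad = grad,
    Kd = Kd, I16 = as.vector(I16), J16 = as.vector(J16),
    robin_facets = rfac, robin_area = rarea,
    Ir = as.vector(Ir), Jr = as.vector(Jr), Mr = Mr,
    dirichlet = if (untagged) integer(0) else boundary_nodes(mesh, "inlet"),
    h_elem = (6 * sqrt(2) * vol)^(1 / 3)   # regular-tet equivalent size
  ), class = "fe_structure")
}

## element mean of a nodal scalar field
elem_mean <- function(fs, c_nodal) {
  (c_nodal[fs$tets[, 1]] + c_nodal[fs$tets[, 2]] +
   c_nodal[fs$tets[, 3]] + c_nodal[fs$tets[, 4]]) / 4
}

## element mean of a nodal vector field (n x 3) -> m x 3
elem_mean_vec <- function(fs, v_nodal) {
  (v_nodal[fs$tets[, 1], , drop = FALSE] +
   v_nodal[fs$tets[, 2], , drop = FALSE] +
   v_nodal[fs$tets[, 3], , drop = FALSE] +
   v_nodal[fs$tets[, 4], , drop = FALSE]) / 4
}

#' Assemble the steady advection-diffusion system
#'
#' Builds the sparse operator and load vector for
#' `-div(nu grad c) + v . grad c = 0` with Robin ion release
#' `-nu dc/dn = r (c - 1)` on the solid interface, natural (zero-flux)
#' outlet, and `c = 0` imposed on inlet nodes by symmetric elimination.
#' Diffusion uses exact P1 formulas; advection uses one-point quadrature
#' with the element-averaged velocity. Optional SUPG stabilization adds
#' the streamline term with the standard coth-rule parameter.
#'
#' @param fs an [fe_structure()].
#' @param nu_elem per-element diffusivity (um^2/s), length `m`.
#' @param adv_elem per-element advection velocity (m x 3, um/s), or `NULL`
#'   for pure diffusion.
#' @param r_eff effective Robin release-rate coefficient (um/s).
#' @param supg logical, add SUPG stabilization.
#' @return list with sparse matrix `K` (dgCMatrix, Dirichlet rows/columns
#'   reduced to identity), load `f`, and `dirichlet` node indices.
#' @export
assemble_system <- function(fs, nu_elem, adv_elem = NULL, r_eff = 0,
                            supg = FALSE) {
  if (length(nu_elem) == 1L) nu_elem <- rep(nu_elem, fs$m)
  if (anyNA(nu_elem) || any(!is.finite(nu_elem)))
    stop("NaN/Inf in diffusivity field")
  vals <- fs$Kd * nu_elem                  # recycle down columns

  if (!is.null(adv_elem)) {
    if (anyNA(adv_elem)) stop("NaN in advection field")
    vg <- lapply(fs$grad, function(g) rowSums(adv_elem * g))  # v . grad N_j
    adv <- matrix(0, fs$m, 16L)
    for (i in 1:4) for (j in 1:4)
      adv[, (i - 1L) * 4L + j] <- fs$vol / 4 * vg[[j]]
    vals <- vals + adv
    if (supg) {
      speed <- sqrt(rowSums(adv_elem^2))
      pe <- speed * fs$h_elem / (2 * nu_elem)
      tau <- ifelse(pe > 1e-8,
                    fs$h_elem / (2 * pmax(speed, 1e-300)) *
                      (1 / tanh(pe) - 1 / pe),
                    0)
      for (i in 1:4) for (j in 1:4)
        vals[, (i - 1L) * 4L + j] <- vals[, (i - 1L) * 4L + j] +
          tau * fs$vol * vg[[i]] * vg[[j]]
    }
  }

  I <- fs$I16; J <- fs$J16; V <- as.vector(vals)
  f <- numeric(fs$n)
  if (r_eff > 0 && nrow(fs$robin_facets) > 0) {
    I <- c(I, fs$Ir); J <- c(J, fs$Jr)
    V <- c(V, as.vector(fs$Mr * r_eff))
    load <- r_eff * fs$robin_area / 3
    for (i in 1:3) {
      contrib <- tapply(load, fs$robin_facets[, i], sum)
      idx <- as.integer(names(contrib))
      f[idx] <- f[idx] + as.vector(contrib)
    }
  }

  ## Dirichlet c = 0 on inlet nodes: drop coupled triplets, unit diagonal.
  dir <- fs$dirichlet
  if (length(dir)) {
    isdir <- logical(fs$n)
    isdir[dir] <- TRUE
    keep <- !(isdir[I] | isdir[J])
    I <- c(I[keep], dir); J <- c(J[keep], dir)
    V <- c(V[keep], rep(1, length(dir)))
    f[dir] <- 0
  }

  K <- Matrix::sparseMatrix(i = I, j = J, x = V, dims = c(fs$n, fs$n))
  list(K = K, f = f, dirichlet = dir)
}
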