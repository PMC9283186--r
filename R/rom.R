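## Online reduced-basis phase: Galerkin projection of the full-order
## operator onto the POD modes inside the Picard loop.

#' Train a reduced basis from a snapshot set
#'
#' Dispatches the four POD variants. The local variants need the query
#' point (neighbourhoods are query-dependent); the quadratic variants
#' expand the centered columns with Hadamard products before the SVD.
#' Combined local-quadratic reduces to neighbours first, then expands.
#'
#' @param snapshots a `snapshot_set`.
#' @param variant `"global"`, `"local"`, `"quadratic"`, or
#'   `"local-quadratic"`.
#' @param eps truncation tolerance of the spectrum-amplitude criterion.
#' @param mu query point (required by the local variants).
#' @param n neighbourhood size for the local variants.
#' @param ranges parameter ranges for neighbour normalization.
#' @param memory_cap_bytes guard passed to [quadratic_expand()].
#' @return a `reduced_basis` (see [pod_basis()]).
#' @export
train_basis <- function(snapshots,
                        variant = c("global", "local", "quadratic",
                                    "local-quadratic"),
                        eps = 1e-2, mu = NULL, n = 10L,
                        ranges = default_ranges(),
                        memory_cap_bytes = 2e9) {
  variant <- match.arg(variant)
  if (variant %in% c("local", "local-quadratic")) {
    if (is.null(mu)) stop("local variants need the query point mu")
    sel <- select_neighbors(mu, snapshots$mu, n, ranges)
    lc <- local_center(snapshots, sel$indices)
    X <- lc$X
    ctr <- lc$mean
    prov <- sprintf("local(%d)", n)
  } else {
    X <- snapshots$X
    ctr <- snapshots$mean
    prov <- "global"
  }
  if (variant %in% c("quadratic", "local-quadratic")) {
    X <- quadratic_expand(X, memory_cap_bytes)
    prov <- if (variant == "quadratic") "quadratic"
            else sprintf("local-quadratic(%d)", n)
  }
  if (all(X == 0)) {
    ## degenerate case (single snapshot, or identical snapshots): the
    ## centering vector already reproduces every training solution
    return(structure(list(U = matrix(0, nrow(X), 0L), sigma = numeric(0),
                          k = 0L, eps = eps, centering = ctr,
                          provenance = prov),
                     class = "reduced_basis"))
  }
  pod_basis(X, eps, centering = ctr, provenance = prov)
}

#' Reduced-order Picard solve
#'
#' Each Picard iteration assembles the full-order operator at the current
#' reconstructed concentration, projects it onto the k modes,
#' `[U' K U] z = U' (f - K cbar)`, solves the dense k x k system and
#' reconstructs `c = cbar + U z`. Stopping rule and tolerance match the
#' full-order solver; the initial guess is `z = 0`.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param mu a [parameter_point()].
#' @param rbasis a `reduced_basis` trained for this mesh.
#' @param basis a [velocity_basis()].
#' @param settings a [solver_settings()] list.
#' @param fs optional precomputed [fe_structure()].
#' @return object of class `reduced_solution`: coefficients `z`,
#'   reconstructed nodal field `c`, `k`, `iterations`, `mu`.
#' @export
reduced_solve <- function(mesh, mu, rbasis, basis,
                          settings = solver_settings(), fs = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh)
  U <- rbasis$U
  cbar <- rbasis$centering
  if (is.null(cbar)) stop("reduced basis carries no centering vector")
  if (nrow(U) != fs$n) stop("reduced basis does not match the mesh dimension")

  adv <- combine_velocity(basis, mu[["v"]], mu[["gamma"]], mu[["beta"]])
  adv_e <- elem_mean_vec(fs, adv$field)
  r_eff <- mu[["r"]] * settings$r_scale
  D_SE <- stokes_einstein(mu[["eta"]], settings$constants)$um2_s

  if (rbasis$k == 0L) {  # degenerate basis: reconstruction is the centering
    return(structure(list(z = numeric(0), c = cbar, k = 0L, iterations = 0L,
                          residuals = numeric(0), mu = mu,
                          provenance = rbasis$provenance),
                     class = "reduced_solution"))
  }
  z <- numeric(rbasis$k)
  c_old <- cbar + as.vector(U %*% z)
  converged <- FALSE
  residuals <- numeric(0)
  for (it in seq_len(settings$max_iter)) {
    nu_e <- D_SE * 10^(-mu[["alpha"]] * elem_mean(fs, c_old))
    sys <- assemble_system(fs, nu_e, adv_e, r_eff, supg = settings$supg)
    KU <- as.matrix(sys$K %*% U)
    A <- crossprod(U, KU)
    b <- as.vector(crossprod(U, sys$f - as.vector(sys$K %*% cbar)))
    z <- tryCatch(solve(as.matrix(A), as.vector(b)),
                  error = function(e)
                    stop("reduced matrix is singular: ", conditionMessage(e)))
    c_new <- cbar + as.vector(U %*% z)
    nrm <- sqrt(sum(c_new^2))
    res <- if (nrm > 0) sqrt(sum((c_new - c_old)^2)) / nrm else 0
    residuals <- c(residuals, res)
    c_old <- c_new
    if (res < settings$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("reduced Picard did not converge in %d iterations (residuals: %s)",
                 settings$max_iter,
                 paste(format(utils::tail(residuals, 5), digits = 3),
                       collapse = ", ")))
  structure(list(z = z, c = c_old, k = rbasis$k, iterations = it,
                 residuals = residuals, mu = mu,
                 provenance = rbasis$provenance),
            class = "reduced_solution")
}

#' Relative Euclidean error of a reduced solution
#'
#' `||c_rom - c_fe||_2 / ||c_fe||_2`, the error measure used to assess
#' reduced-order solutions against the full-order reference.
#'
#' @param c_rom,c_fe nodal fields of equal length (vectors or solution
#'   objects with a `c` field).
#' @return scalar relative error.
#' @export
relative_error <- function(c_rom, c_fe) {
  if (is.list(c_rom)) c_rom <- c_rom$c
  if (is.list(c_fe)) c_fe <- c_fe$c
  if (length(c_rom) != length(c_fe)) stop("field lengths differ")
  ref <- sqrt(sum(c_fe^2))
  if (ref == 0) stop("reference field is identically zero")
  sqrt(sum((c_rom - c_fe)^2)) / ref
}
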