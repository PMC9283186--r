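## Full-order transport solver: steady advection-diffusion of Ca2+ with
## concentration-dependent Stokes-Einstein diffusivity, solved by Picard
## fixed-point iteration on the assembled sparse system.

#' Physical constants for the Stokes-Einstein diffusivity
#'
#' @param k_B Boltzmann constant (J/K).
#' @param T_celsius temperature in degrees Celsius (converted internally
#'   to kelvin as `T + 273.15`).
#' @param rho ionic radius of Ca2+ (m); default 114 pm.
#' @return named list of constants, with `T_kelvin` included.
#' @export
physical_constants <- function(k_B = 1.38e-23, T_celsius = 37,
                               rho = 114e-12) {
  list(k_B = k_B, T_celsius = T_celsius, T_kelvin = T_celsius + 273.15,
       rho = rho)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D_SE = k_B T / (6 pi eta rho)` for an ion of radius `rho` in a fluid
#' of dynamic viscosity `eta`.
#'
#' @param eta dynamic viscosity (Pa s), > 0.
#' @param constants a [physical_constants()] list.
#' @return list with `m2_s` (SI, m^2/s) and `um2_s` (internal units,
#'   um^2/s = m2_s * 1e12).
#' @examples
#' stokes_einstein(1e-3)$m2_s   # ~2e-9 m^2/s for water-like viscosity
#' @export
stokes_einstein <- function(eta, constants = physical_constants()) {
  if (!is.finite(eta) || eta <= 0) stop("viscosity eta must be positive")
  D <- constants$k_B * constants$T_kelvin / (6 * pi * eta * constants$rho)
  list(m2_s = D, um2_s = D * 1e12)
}

#' Concentration-dependent diffusivity
#'
#' `nu(c) = D_SE 10^(-alpha c)`: diffusivity decreases with local crowding;
#' `alpha = 0` gives the constant free-solution value and `alpha = 1`
#' reduces it by one order of magnitude where `c = 1`.
#'
#' @param c nodal (or element) concentration values.
#' @param alpha dimensionless crowding exponent in `[0, 1]`.
#' @param eta viscosity (Pa s).
#' @param constants a [physical_constants()] list.
#' @return diffusivity values in um^2/s, same shape as `c`.
#' @export
diffusivity <- function(c, alpha, eta, constants = physical_constants()) {
  if (any(!is.finite(c))) stop("concentration field contains non-finite values")
  stokes_einstein(eta, constants)$um2_s * 10^(-alpha * c)
}

#' Parameter point of the six-dimensional model space
#'
#' @param v mean interstitial speed (um/s).
#' @param gamma,beta inflow angles (degrees).
#' @param alpha crowding exponent (dimensionless).
#' @param eta viscosity (Pa s).
#' @param r release rate in printed units (scaled by `r_scale` in the
#'   solver settings to an effective um/s Robin coefficient).
#' @return named numeric vector of class `parameter_point`, in the fixed
#'   order (v, gamma, beta, alpha, eta, r).
#' @export
parameter_point <- function(v, gamma, beta, alpha, eta, r) {
  structure(c(v = v, gamma = gamma, beta = beta, alpha = alpha,
              eta = eta, r = r),
            class = "parameter_point")
}

#' Modelled parameter ranges
#'
#' The six parameter intervals of the transport model: `v` in [1, 60]
#' um/s, angles in [10, 80] degrees, `alpha` in [0, 1], `eta` in
#' [5e-4, 1.5e-3] Pa s, `r` in [0.5, 2].
#'
#' @return named list of length-2 numeric ranges in the fixed parameter
#'   order.
#' @export
default_ranges <- function() {
  list(v = c(1, 60), gamma = c(10, 80), beta = c(10, 80),
       alpha = c(0, 1), eta = c(5e-4, 1.5e-3), r = c(0.5, 2))
}

#' Solver settings
#'
#' @param tol Picard stopping tolerance on the relative Euclidean norm of
#'   the update, default 1e-8.
#' @param max_iter Picard iteration cap, default 50.
#' @param r_scale effective Robin coefficient per printed release-rate
#'   unit (um/s); default 10, chosen so the printed range [0.5, 2] spans
#'   Robin numbers of order one on a ~200 um pore.
#' @param supg logical, SUPG stabilization (default off; element Peclet
#'   numbers are below one across the default ranges).
#' @param constants a [physical_constants()] list.
#' @return named list of settings.
#' @export
solver_settings <- function(tol = 1e-8, max_iter = 50L, r_scale = 10,
                            supg = FALSE, constants = physical_constants()) {
  list(tol = tol, max_iter = as.integer(max_iter), r_scale = r_scale,
       supg = supg, constants = constants)
}

#' Full-order Picard solve of the nonlinear transport problem
#'
#' Iterates `K(mu, c_old) c_new = f(mu)` from `c = 0` until the relative
#' Euclidean update norm drops below the tolerance. For `alpha = 0` the
#' operator is concentration-independent and the loop exits on the second
#' iteration.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param mu a [parameter_point()].
#' @param basis a [velocity_basis()] for the same mesh.
#' @param settings a [solver_settings()] list.
#' @param fs optional precomputed [fe_structure()].
#' @return object of class `concentration_field`: nodal `c`, `mu`,
#'   `iterations`, `converged`, `residuals` (per-iteration relative
#'   updates), and `bounds_violation` (max excursion outside [0, 1]).
#' @export
picard_solve <- function(mesh, mu, basis, settings = solver_settings(),
                         fs = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh)
  if (!is.null(basis$fingerprint)) {
    ## fingerprint check is advisory: basis must come from this mesh
    stopifnot(nrow(basis$vx) == fs$n)
  }
  adv <- combine_velocity(basis, mu[["v"]], mu[["gamma"]], mu[["beta"]])
  adv_e <- elem_mean_vec(fs, adv$field)
  r_eff <- mu[["r"]] * settings$r_scale
  D_SE <- stokes_einstein(mu[["eta"]], settings$constants)$um2_s

  c_old <- numeric(fs$n)
  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    nu_e <- D_SE * 10^(-mu[["alpha"]] * elem_mean(fs, c_old))
    sys <- assemble_system(fs, nu_e, adv_e, r_eff, supg = settings$supg)
    c_new <- as.vector(Matrix::solve(sys$K, sys$f))
    nrm <- sqrt(sum(c_new^2))
    res <- if (nrm > 0) sqrt(sum((c_new - c_old)^2)) / nrm else 0
    residuals <- c(residuals, res)
    c_old <- c_new
    if (res < settings$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("Picard did not converge in %d iterations (last residual %.3e)",
                 settings$max_iter, residuals[length(residuals)]))

  viol <- max(0, max(c_old) - 1, -min(c_old))
  if (viol > 1e-6)
    message(sprintf("concentration outside [0,1] by %.2e (coarse-mesh overshoot)",
                    viol))
  structure(list(c = c_old, mu = mu, iterations = it, converged = converged,
                 residuals = residuals, bounds_violation = viol),
            class = "concentration_field")
}
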