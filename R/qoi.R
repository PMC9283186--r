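## Quantity of interest: the percentage of fluid volume where the
## concentration exceeds a threshold (default 0.9 of saturation), used as
## a proxy for regions of expected bone formation.

## Sorting network for rows of an m x 4 matrix, descending.
sort4_desc <- function(Y) {
  cs <- function(M, i, j) {  # compare-swap so column i >= column j
    lo <- pmin(M[, i], M[, j])
    M[, i] <- pmax(M[, i], M[, j])
    M[, j] <- lo
    M
  }
  Y <- cs(Y, 1, 2); Y <- cs(Y, 3, 4); Y <- cs(Y, 1, 3)
  Y <- cs(Y, 2, 4); Y <- cs(Y, 2, 3)
  Y
}

## Exact fraction of each tetrahedron's volume where the linear
## interpolant of the vertex values exceeds zero. Uses the closed-form
## distribution function of a linear field over a simplex; all divisors
## are strictly positive in each sign case, so the evaluation is
## cancellation-free.
tet_positive_fraction <- function(Y) {
  Y <- sort4_desc(Y)
  y1 <- Y[, 1]; y2 <- Y[, 2]; y3 <- Y[, 3]; y4 <- Y[, 4]
  np <- rowSums(Y > 0)
  f <- numeric(nrow(Y))
  f[np == 4] <- 1

  i1 <- np == 1
  f[i1] <- y1[i1]^3 / ((y1[i1] - y2[i1]) * (y1[i1] - y3[i1]) *
                       (y1[i1] - y4[i1]))
  i3 <- np == 3
  f[i3] <- 1 - (-y4[i3])^3 / ((y1[i3] - y4[i3]) * (y2[i3] - y4[i3]) *
                              (y3[i3] - y4[i3]))
  i2 <- np == 2
  if (any(i2)) {
    A <- y1[i2]; B <- y2[i2]; C <- y3[i2]; D <- y4[i2]
    P <- A^2 * B^2 - A^2 * B * C - A^2 * B * D + A^2 * C * D -
      A * B^2 * C - A * B^2 * D + A * B * C * D + B^2 * C * D
    f[i2] <- P / ((A - C) * (A - D) * (B - C) * (B - D))
  }
  f
}

#' High-concentration volume ratio
#'
#' Computes the exact volume of the sub-region where the P1 interpolant
#' of the nodal concentration exceeds the threshold (per-tetrahedron
#' linear level-set analysis), as a percentage of the total fluid volume:
#' `QoI = V / V_Omega * 100`.
#'
#' @param mesh a `tet_mesh`.
#' @param c nodal concentration (vector or a `concentration_field`).
#' @param threshold saturation fraction in (0, 1); default 0.9.
#' @return object of class `qoi_result`: `qoi` (percent), `V` (um^3),
#'   `V_omega` (um^3), `threshold`.
#' @export
qoi_volume_ratio <- function(mesh, c, threshold = 0.9) {
  if (is.list(c)) c <- c$c
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  Y <- matrix(c[mesh$tets], ncol = 4L) - threshold
  V <- sum(mesh$vol * tet_positive_fraction(Y))
  structure(list(qoi = V / mesh$V_omega * 100, V = V,
                 V_omega = mesh$V_omega, threshold = threshold),
            class = "qoi_result")
}

#' @export
print.qoi_result <- function(x, ...) {
  cat(sprintf("QoI = %.2f%% of fluid volume above c = %g (V = %.4g um^3)\n",
              x$qoi, x$threshold, x$V))
  invisible(x)
}

#' Per-element high-concentration flag
#'
#' Classifies each tetrahedron as high-concentration when its mean nodal
#' value exceeds the threshold; the cheap element-wise counterpart of
#' [qoi_volume_ratio()] used for figure-style masks.
#'
#' @inheritParams qoi_volume_ratio
#' @return logical vector, one flag per element.
#' @export
high_concentration_mask <- function(mesh, c, threshold = 0.9) {
  if (is.list(c)) c <- c$c
  rowMeans(matrix(c[mesh$tets], ncol = 4L)) > threshold
}

#' Parametric sweep of the QoI
#'
#' Varies one parameter over given values with the others fixed, solving
#' full-order at each value and, optionally, with reduced-order variants
#' trained from a snapshot set; reports QoI, relative solution error and
#' QoI absolute error per row.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param basis a [velocity_basis()].
#' @param varied name of the swept parameter.
#' @param values numeric vector of values for the swept parameter; values
#'   outside the modelled range produce a warning, not an error.
#' @param fixed a [parameter_point()] providing the other parameters.
#' @param variants character vector of ROM variants (see [train_basis()]);
#'   empty for full-order only.
#' @param snapshots a `snapshot_set` (required when `variants` nonempty).
#' @param eps,n ROM truncation tolerance and local neighbourhood size.
#' @param settings a [solver_settings()] list.
#' @param threshold QoI threshold.
#' @param fs optional precomputed [fe_structure()].
#' @param csv optional path; when given the report is also written as CSV.
#' @return data.frame of class `sweep_report` with columns `value`,
#'   `solver`, `k`, `qoi_percent`, `Er`, `qoi_abs_error`, `picard_iters`,
#'   `status`.
#' @export
sweep_qoi <- function(mesh, basis, varied, values, fixed,
                      variants = character(), snapshots = NULL,
                      eps = 1e-2, n = 10L,
                      settings = solver_settings(), threshold = 0.9,
                      fs = NULL, csv = NULL) {
  rg <- default_ranges()
  if (!varied %in% names(rg)) stop("unknown parameter: ", varied)
  if (any(values < rg[[varied]][1] | values > rg[[varied]][2]))
    warning("sweep values outside the modelled range for ", varied)
  if (length(variants) && is.null(snapshots))
    stop("ROM variants requested but no snapshot set given")
  if (is.null(fs)) fs <- fe_structure(mesh)

  rows <- list()
  for (val in values) {
    mu <- fixed
    mu[[varied]] <- val
    mu <- do.call(parameter_point, as.list(mu))
    fe <- tryCatch(picard_solve(mesh, mu, basis, settings, fs = fs),
                   error = function(e) e)
    if (inherits(fe, "error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(value = val, solver = "full-order", k = NA_integer_,
                   qoi_percent = NA_real_, Er = NA_real_,
                   qoi_abs_error = NA_real_, picard_iters = NA_integer_,
                   status = conditionMessage(fe))
      next
    }
    q_fe <- qoi_volume_ratio(mesh, fe, threshold)$qoi
    rows[[length(rows) + 1L]] <-
      data.frame(value = val, solver = "full-order", k = NA_integer_,
                 qoi_percent = q_fe, Er = 0, qoi_abs_error = 0,
                 picard_iters = fe$iterations, status = "ok")
    for (variant in variants) {
      res <- tryCatch({
        rb <- train_basis(snapshots, variant, eps = eps, mu = mu, n = n)
        rs <- reduced_solve(mesh, mu, rb, basis, settings, fs = fs)
        q_rom <- qoi_volume_ratio(mesh, rs, threshold)$qoi
        data.frame(value = val, solver = variant, k = rb$k,
                   qoi_percent = q_rom, Er = relative_error(rs, fe),
                   qoi_abs_error = abs(q_rom - q_fe),
                   picard_iters = rs$iterations, status = "ok")
      }, error = function(e)
        data.frame(value = val, solver = variant, k = NA_integer_,
                   qoi_percent = NA_real_, Er = NA_real_,
                   qoi_abs_error = NA_real_, picard_iters = NA_integer_,
                   status = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "varied") <- varied
  attr(report, "fixed") <- fixed
  class(report) <- c("sweep_report", class(report))
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  report
}
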