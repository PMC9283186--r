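## Training-set samplers over the six-parameter space.

#' Corner sampling of the parameter space
#'
#' All combinations of the two extreme values of each range, in the fixed
#' parameter order (v, gamma, beta, alpha, eta, r); six two-valued
#' parameters give the 64-point coarse training set. Degenerate ranges
#' (zero length) are deduplicated.
#'
#' @param ranges named list of length-2 ranges, as [default_ranges()].
#' @return matrix (n_points x n_params) with one parameter point per row,
#'   deterministically ordered (last parameter varies fastest).
#' @export
corner_sampling <- function(ranges = default_ranges()) {
  grid_sampling(ranges, levels = 2L)
}

#' Equidistant grid sampling of the parameter space
#'
#' `levels` equidistant values per range, endpoints included; all
#' combinations in the fixed parameter order. `levels = 2` coincides with
#' [corner_sampling()]; `levels = 3` over six parameters gives 729 points.
#'
#' @param ranges named list of length-2 ranges.
#' @param levels integer >= 2.
#' @return matrix (n_points x n_params), one point per row; rows are
#'   deduplicated (relevant for zero-length ranges) with order preserved.
#' @export
grid_sampling <- function(ranges, levels = 3L) {
  if (levels < 2L) stop("levels must be at least 2")
  vals <- lapply(ranges, function(rg) {
    if (any(!is.finite(rg))) stop("parameter ranges must be finite")
    seq(rg[1], rg[2], length.out = levels)
  })
  ## last parameter varies fastest: reverse, expand, restore order
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_along(vals)), drop = FALSE])
  colnames(g) <- names(ranges)
  unique(g)
}

#' Range-normalized nearest neighbours in parameter space
#'
#' Squared distance `sum_p ((mu_p - mu^i_p) / range_p)^2`, each parameter
#' normalized by the length of its modelled range. Ties are broken by
#' ascending snapshot index (stable order).
#'
#' @param mu query parameter point (named vector or [parameter_point()]).
#' @param points matrix of training points (rows), columns in the fixed
#'   parameter order.
#' @param n number of neighbours, `1 <= n <= nrow(points)`.
#' @param ranges named list of ranges used for normalization (defaults to
#'   the modelled ranges even when training covers a sub-range).
#' @return list with `indices` (length n), `distances` (normalized, same
#'   order) and `mu`.
#' @export
select_neighbors <- function(mu, points, n, ranges = default_ranges()) {
  if (n < 1 || n > nrow(points))
    stop("n must be between 1 and the number of training points")
  if (!is.null(colnames(points))) ranges <- ranges[colnames(points)]
  len <- vapply(ranges, function(rg) diff(range(rg)), numeric(1))
  len[len <= 0] <- 1   # pinned parameter: absolute differences (usually 0)
  q <- as.numeric(mu[colnames(points)])
  z <- sweep(points, 2L, q)
  d <- sqrt(rowSums(sweep(z, 2L, len, `/`)^2))
  ord <- order(d, seq_along(d))
  idx <- ord[seq_len(n)]
  list(indices = idx, distances = unname(d[idx]), mu = q)
}
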