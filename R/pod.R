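## Snapshot handling and proper orthogonal decomposition (POD): offline
## training of the reduced basis in standard, local, quadratic and
## local-quadratic variants.

#' Build a snapshot set by full-order solves
#'
#' Runs the Picard solver at every training point, centers the solutions
#' about their mean, and collects them column-wise. Non-converged points
#' are excluded with a warning; more than 10% failures aborts. Snapshots
#' can be cached to a directory keyed by parameter hash and mesh
#' fingerprint, making the offline phase resumable.
#'
#' @param mesh a tagged `tet_mesh`.
#' @param points training-point matrix (rows), as from [corner_sampling()].
#' @param basis a [velocity_basis()].
#' @param settings a [solver_settings()] list.
#' @param fs optional precomputed [fe_structure()].
#' @param cache_dir optional directory for per-snapshot RDS caching.
#' @return object of class `snapshot_set`: centered matrix `X` (d x n_S),
#'   `mean` (d), `mu` (points actually used), `iterations`, `fingerprint`.
#' @export
build_snapshots <- function(mesh, points, basis,
                            settings = solver_settings(), fs = NULL,
                            cache_dir = NULL) {
  if (is.null(fs)) fs <- fe_structure(mesh)
  fp <- mesh_fingerprint(mesh)
  n_S <- nrow(points)
  sols <- vector("list", n_S)
  iters <- integer(n_S)
  ok <- logical(n_S)
  for (i in seq_len(n_S)) {
    mu <- do.call(parameter_point, as.list(points[i, ]))
    cache <- NULL
    if (!is.null(cache_dir)) {
      key <- paste0(fp, "-", paste(format(points[i, ], digits = 15),
                                   collapse = "_"))
      cache <- file.path(cache_dir, paste0("snap-",
                                           substr(digest_string(key), 1, 16),
                                           ".rds"))
    }
    sol <- if (!is.null(cache) && file.exists(cache)) {
      readRDS(cache)
    } else {
      s <- tryCatch(picard_solve(mesh, mu, basis, settings, fs = fs),
                    error = function(e) e)
      if (!inherits(s, "error") && !is.null(cache)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(s, cache)
      }
      s
    }
    if (inherits(sol, "error")) {
      warning("snapshot ", i, " failed and is excluded: ",
              conditionMessage(sol))
    } else {
      sols[[i]] <- sol$c
      iters[i] <- sol$iterations
      ok[i] <- TRUE
    }
  }
  if (sum(ok) < 0.9 * n_S)
    stop("more than 10% of snapshots failed to converge")
  C <- do.call(cbind, sols[ok])
  cbar <- rowMeans(C)
  structure(list(X = C - cbar, mean = cbar,
                 mu = points[ok, , drop = FALSE],
                 iterations = iters[ok], fingerprint = fp),
            class = "snapshot_set")
}

## md5 of a string (cache keys); serialization-free
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' POD basis by singular value decomposition
#'
#' Thin SVD of the (centered) snapshot matrix; the reduced dimension `k`
#' is the smallest integer whose leading singular values accumulate at
#' least a fraction `1 - eps` of the total spectrum amplitude. Singular
#' values below `1e-12 * sigma_1` are treated as numerical zeros. Mode
#' signs are fixed so the largest-magnitude entry of each mode is
#' positive, making bases reproducible.
#'
#' @param X matrix (d x n_cols) of centered (possibly expanded) snapshots.
#' @param eps truncation tolerance in `[0, 1)`; `eps = 0` keeps the full
#'   numerical rank.
#' @param centering the centering vector the basis is meant to be used
#'   with (stored for the online phase).
#' @param provenance character label (`"global"`, `"local(n)"`, ...).
#' @return object of class `reduced_basis`: `U` (d x k), `sigma` (all
#'   singular values), `k`, `eps`, `centering`, `provenance`.
#' @export
pod_basis <- function(X, eps = 1e-2, centering = NULL,
                      provenance = "global") {
  X <- as.matrix(X)
  if (all(X == 0)) stop("snapshot matrix is identically zero")
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  sigma <- sv$d
  sigma[sigma < 1e-12 * sigma[1]] <- 0
  rank <- sum(sigma > 0)
  cum <- cumsum(sigma)
  k <- which(cum >= (1 - eps) * cum[length(cum)])[1]
  k <- min(k, rank)
  U <- sv$u[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-|entry| positive per mode
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, sigma = sigma, k = k, eps = eps,
                 centering = centering, provenance = provenance),
            class = "reduced_basis")
}

#' Locally centered snapshot columns
#'
#' Rebuilds the raw snapshots for an index set and centers them about
#' their local average (the local analogue of global centering; with the
#' full index set it reduces to the global centering exactly).
#'
#' @param snapshots a `snapshot_set`.
#' @param indices integer vector into the snapshot columns.
#' @return list with `X` (d x n local centered columns) and `mean` (the
#'   local average, a full-order vector).
#' @export
local_center <- function(snapshots, indices) {
  if (!length(indices)) stop("empty neighbour index set")
  raw <- snapshots$X[, indices, drop = FALSE] + snapshots$mean
  lmean <- rowMeans(raw)
  list(X = raw - lmean, mean = lmean)
}

#' Quadratic expansion of centered snapshots
#'
#' Appends to the centered snapshots all unordered componentwise
#' (Hadamard) products, squares included, giving
#' `2 n_S + n_S (n_S - 1) / 2` columns. Products are taken of the
#' centered snapshots and the expanded matrix is not re-centered.
#'
#' @param Xc matrix (d x n_S) of centered columns.
#' @param memory_cap_bytes guard for the expanded matrix size; exceeding
#'   it raises an error suggesting the local variant.
#' @return matrix with the original columns followed by products
#'   (1,1), (1,2), ..., (n,n) in row-major upper-triangular order.
#' @export
quadratic_expand <- function(Xc, memory_cap_bytes = 2e9) {
  n_S <- ncol(Xc)
  d <- nrow(Xc)
  n_cols <- 2 * n_S + n_S * (n_S - 1) / 2
  if (n_cols * d * 8 > memory_cap_bytes)
    stop(sprintf(paste0("quadratic expansion would need %d columns ",
                        "(%.1f GB); use the local-quadratic variant"),
                 n_cols, n_cols * d * 8 / 1e9))
  prod_cols <- matrix(0, d, n_cols - n_S)
  p <- 0L
  for (i in seq_len(n_S)) for (j in i:n_S) {
    p <- p + 1L
    prod_cols[, p] <- Xc[, i] * Xc[, j]
  }
  cbind(Xc, prod_cols)
}

#' Predicted column count of the quadratic expansion
#' @param n_S number of snapshots.
#' @return `2 n_S + n_S (n_S - 1) / 2`.
#' @export
quadratic_ncol <- function(n_S) 2 * n_S + n_S * (n_S - 1) / 2
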