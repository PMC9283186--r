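test_that("corner and grid sampling enumerate the training sets", {
  pts <- corner_sampling()
  expect_equal(nrow(pts), 64L)
  expect_equal(colnames(pts), c("v", "gamma", "beta", "alpha", "eta", "r"))
  expect_equal(nrow(unique(pts)), 64L)
  ## deterministic order: first row all minima, last all maxima, r fastest
  rg <- default_ranges()
  expect_equal(unname(pts[1, ]), unname(vapply(rg, `[`, numeric(1), 1)))
  expect_equal(unname(pts[64, ]), unname(vapply(rg, `[`, numeric(1), 2)))
  expect_equal(unname(pts[2, ] - pts[1, ]),
               c(0, 0, 0, 0, 0, diff(rg$r)))

  g3 <- grid_sampling(rg, 3)
  expect_equal(nrow(g3), 729L)
  mid <- vapply(rg, mean, numeric(1))
  expect_true(any(apply(g3, 1, function(p) all(p == mid))))
  expect_equal(grid_sampling(rg, 2), pts)
  expect_error(grid_sampling(rg, 1), "at least 2")

  expect_equal(nrow(corner_sampling(list(v = c(1, 60)))), 2L)
})

test_that("POD singular values match the Gram-matrix oracle", {
  set.seed(7)
  for (trial in 1:3) {
    X <- matrix(rnorm(32), 8, 4)
    rb <- pod_basis(X, eps = 0)
    sig_oracle <- sqrt(sort(eigen(crossprod(X), symmetric = TRUE)$values,
                            decreasing = TRUE))
    expect_equal(rb$sigma, sig_oracle, tolerance = 1e-10)
    expect_equal(crossprod(rb$U), diag(rb$k), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rb$k, 4L)  # random matrices are full rank
  }
})

test_that("truncation keeps the minimal k for the amplitude criterion", {
  set.seed(8)
  X <- matrix(rnorm(48), 8, 6)
  for (eps in c(0.02, 0.1, 0.3)) {
    rb <- pod_basis(X, eps)
    s <- rb$sigma
    expect_gte(sum(s[seq_len(rb$k)]), (1 - eps) * sum(s))
    if (rb$k > 1)
      expect_lt(sum(s[seq_len(rb$k - 1)]), (1 - eps) * sum(s))
  }
  ## rank-1 matrix: a single mode suffices for any eps
  X1 <- outer(rnorm(8), rnorm(5))
  expect_equal(pod_basis(X1, 0.5)$k, 1L)
  expect_equal(pod_basis(X1, 0)$k, 1L)     # numerical rank
  ## rank-2 with eps = 0 keeps exactly the rank
  X2 <- outer(rnorm(8), rnorm(5)) + outer(rnorm(8), rnorm(5))
  expect_equal(pod_basis(X2, 0)$k, 2L)
  expect_error(pod_basis(matrix(0, 4, 2), 0.1), "zero")
})

test_that("neighbour selection uses range-normalized distances", {
  ## hand case: normalization inverts the raw Euclidean ordering
  points <- rbind(A = c(2, 0), B = c(0, 9))
  colnames(points) <- c("p1", "p2")
  ranges <- list(p1 = c(0, 2), p2 = c(0, 10))
  q <- c(p1 = 0, p2 = 0)
  sel <- select_neighbors(q, points, 1, ranges)
  expect_equal(sel$indices, 2L)                # B wins after normalization
  expect_equal(sel$distances, 0.9, tolerance = 1e-14)
  ## raw distances would have picked A (|A| = 2 < |B| = 9)

  expect_equal(select_neighbors(q, points, 2, ranges)$indices, c(2L, 1L))
  expect_error(select_neighbors(q, points, 3, ranges), "between 1")

  ## a query equal to a training point sits at distance zero
  sel0 <- select_neighbors(c(p1 = 2, p2 = 0), points, 1, ranges)
  expect_equal(sel0$indices, 1L)
  expect_equal(sel0$distances, 0)

  ## ties break by ascending snapshot index
  dup <- rbind(c(1, 1), c(1, 1), c(0, 0))
  colnames(dup) <- c("p1", "p2")
  st <- select_neighbors(c(p1 = 1, p2 = 1), dup, 2, ranges)
  expect_equal(st$indices, c(1L, 2L))
})

test_that("local centering reduces to global centering on the full set", {
  snaps <- list(X = matrix(rnorm(20), 5, 4), mean = rnorm(5))
  snaps$X <- snaps$X - rowMeans(snaps$X)
  class(snaps) <- "snapshot_set"
  lc <- local_center(snaps, 1:4)
  expect_equal(lc$X, snaps$X, tolerance = 1e-12)
  expect_equal(lc$mean, snaps$mean, tolerance = 1e-12)

  one <- local_center(snaps, 2)
  expect_equal(one$X, matrix(0, 5, 1), tolerance = 1e-14, ignore_attr = TRUE)

  two <- local_center(snaps, c(1, 3))
  diffc <- (snaps$X[, 1] - snaps$X[, 3]) / 2
  expect_equal(two$X[, 1], diffc, tolerance = 1e-13)
  expect_equal(two$X[, 2], -diffc, tolerance = 1e-13)
})

test_that("quadratic expansion enumerates Hadamard products in order", {
  expect_equal(ncol(quadratic_expand(matrix(1:2, 2, 1))), 2L)
  expect_equal(quadratic_ncol(729), 266814)

  Xc <- rbind(c(1, 2, 3), c(4, 5, 6))
  Xq <- quadratic_expand(Xc)
  expect_equal(ncol(Xq), 9L)
  expect_equal(Xq[, 1:3], Xc, ignore_attr = TRUE)
  expect_equal(Xq[, 4], c(1, 16))    # (1,1)
  expect_equal(Xq[, 5], c(2, 20))    # (1,2)
  expect_equal(Xq[, 6], c(3, 24))    # (1,3)
  expect_equal(Xq[, 7], c(4, 25))    # (2,2)
  expect_equal(Xq[, 8], c(6, 30))    # (2,3)
  expect_equal(Xq[, 9], c(9, 36))    # (3,3)

  expect_error(quadratic_expand(matrix(1, 1000, 800),
                                memory_cap_bytes = 1e6), "local")
})

test_that("snapshot building centers, deduplicates work, and fails loudly", {
  mesh <- duct_fixture(4)
  fs <- fe_structure(mesh)
  vb <- velocity_basis(mesh, fs = fs)
  p1 <- c(v = 20, gamma = 45, beta = 45, alpha = 0, eta = 1e-3, r = 1)
  pts <- rbind(p1, p1 * c(1.5, 1, 1, 1, 1, 1), p1)

  snaps <- suppressWarnings(build_snapshots(mesh, pts, vb, fs = fs))
  expect_equal(ncol(snaps$X), 3L)
  expect_lt(max(abs(rowSums(snaps$X))), 1e-10 * max(1, norm(snaps$X, "F")))
  expect_equal(snaps$X[, 1], snaps$X[, 3], tolerance = 1e-14)

  one <- suppressWarnings(build_snapshots(mesh, pts[1, , drop = FALSE], vb,
                                          fs = fs))
  expect_equal(one$X, matrix(0, nrow(one$X), 1), ignore_attr = TRUE)

  ## all snapshots failing (iteration cap 1) aborts the offline phase
  expect_error(
    suppressWarnings(build_snapshots(
      mesh, rbind(p1 + c(0, 0, 0, 0.9, 0, 0)), vb,
      solver_settings(max_iter = 1L), fs = fs)),
    "10%")
})
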