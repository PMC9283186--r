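## Voxel-grid utilities: face-connectivity labelling and conversion of a
## boolean fluid mask into a conforming linear-tetrahedra mesh.

#' Face-connected components of a voxel mask
#'
#' Labels the TRUE voxels of a 3-D logical array into 6-neighbourhood
#' (face-adjacent) connected components by multi-source frontier expansion.
#'
#' @param mask 3-D logical array.
#' @return integer array of the same shape: 0 for FALSE voxels, otherwise a
#'   component label; labels are ordered by discovery.
#' @keywords internal
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  todo <- mask
  comp <- 0L
  while (any(todo)) {
    comp <- comp + 1L
    seed <- which(todo)[1L]
    frontier <- array(FALSE, dm)
    frontier[seed] <- TRUE
    visited <- frontier
    while (any(frontier)) {
      grown <- shift_or(frontier)
      frontier <- grown & todo & !visited
      visited <- visited | frontier
    }
    lab[visited] <- comp
    todo <- todo & !visited
  }
  lab
}

## union of the six face-shifts of a logical array (used by flood fill)
shift_or <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  if (n1 > 1) {
    out[-1, , ] <- out[-1, , ] | a[-n1, , ]
    out[-n1, , ] <- out[-n1, , ] | a[-1, , ]
  }
  if (n2 > 1) {
    out[, -1, ] <- out[, -1, ] | a[, -n2, ]
    out[, -n2, ] <- out[, -n2, ] | a[, -1, ]
  }
  if (n3 > 1) {
    out[, , -1] <- out[, , -1] | a[, , -n3]
    out[, , -n3] <- out[, , -n3] | a[, , -1]
  }
  out
}

#' Keep the largest face-connected component of a mask
#'
#' @param mask 3-D logical array.
#' @return list with `mask` (largest component only), `n_components`, and
#'   `fraction` (largest-component voxel count / total TRUE count).
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) stop("mask is empty: no fluid voxels")
  counts <- tabulate(lab[lab > 0L])
  best <- which.max(counts)
  list(mask = lab == best, n_components = length(counts),
       fraction = counts[best] / sum(counts))
}

## Kuhn subdivision of the unit cube into 6 tetrahedra sharing the main
## diagonal (0,0,0)-(1,1,1). Translation-invariant, hence globally
## conforming across face-adjacent voxels. Rows: corner offsets; each
## permutation of the axes yields one tetrahedron.
kuhn_templates <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    e <- diag(3)
    v0 <- c(0, 0, 0)
    v1 <- v0 + e[p[1], ]
    v2 <- v1 + e[p[2], ]
    v3 <- c(1, 1, 1)
    rbind(v0, v1, v2, v3)
  })
}

#' Convert a voxel fluid mask to a conforming tetrahedral mesh
#'
#' Each fluid voxel is split into six tetrahedra along its main diagonal
#' (Kuhn subdivision); the split is translation-invariant so shared faces of
#' adjacent voxels conform exactly. All tetrahedra are re-oriented to
#' positive signed volume.
#'
#' @param mask 3-D logical array of fluid voxels; must be non-empty and
#'   face-connected (use [largest_component()] upstream).
#' @param box a [box_spec()] whose voxel counts equal `dim(mask)`.
#' @return an (untagged) `tet_mesh`; see [tet_mesh()].
#' @export
voxel_to_tets <- function(mask, box) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical array")
  if (!all(dim(mask) == box$n)) stop("mask dimensions do not match box voxel counts")
  if (!any(mask)) stop("mask is empty: no fluid voxels")
  lab <- label_components(mask)
  if (max(lab) > 1L)
    stop("fluid mask is not face-connected (", max(lab), " components); ",
         "apply the largest-component filter first")

  h <- box$h
  np <- box$n + 1L                  # lattice points per axis
  idx <- which(mask, arr.ind = TRUE) # voxel (i,j,k), 1-based
  nv <- nrow(idx)

  ## global lattice node id for corner offsets (0/1) of each voxel
  nid <- function(di, dj, dk) {
    (idx[, 1] - 1L + di) + np[1] * ((idx[, 2] - 1L + dj) +
      np[2] * (idx[, 3] - 1L + dk)) + 1L
  }

  tmpl <- kuhn_templates()
  tets <- matrix(0L, nrow = 6L * nv, ncol = 4L)
  for (t in seq_along(tmpl)) {
    off <- tmpl[[t]]
    for (v in 1:4) {
      tets[seq.int(t, by = 6L, length.out = nv), v] <-
        nid(off[v, 1], off[v, 2], off[v, 3])
    }
  }

  used <- sort(unique(as.vector(tets)))
  remap <- integer(np[1] * np[2] * np[3])
  remap[used] <- seq_along(used)
  tets[] <- remap[tets]

  g0 <- used - 1L
  i <- g0 %% np[1]
  j <- (g0 %/% np[1]) %% np[2]
  k <- g0 %/% (np[1] * np[2])
  nodes <- cbind(x = i * h, y = j * h, z = k * h)

  tet_mesh(nodes, tets, h = h, box = box)
}
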