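## Tetrahedral mesh container for the interstitial-fluid domain.
## Nodes are in micrometres; node indexing is 1-based throughout the
## package (files written to disk use the conventions of their format).

INLET <- 1L
OUTLET <- 2L
SOLID <- 3L

.tag_names <- c("inlet", "outlet", "solid")

#' Tetrahedral mesh of a scaffold fluid domain
#'
#' Container for a linear-tetrahedra (C3D4) discretization of the pore
#' space. Tetrahedra are re-oriented to positive signed volume on
#' construction and the boundary facets (triangles belonging to exactly one
#' tetrahedron) are extracted with outward orientation. Boundary tags
#' partition the surface into inlet (Dirichlet c = 0), outlet (free
#' outflow) and solid scaffold interface (Robin ion release).
#'
#' @param nodes numeric matrix (n x 3) of coordinates in um.
#' @param tets integer matrix (m x 4) of 1-based node indices.
#' @param h optional voxel resolution the mesh was generated at (um).
#' @param box optional [box_spec()] of the generating lattice.
#' @param metadata named list of provenance (generator spec, seed,
#'   achieved porosity, ...).
#' @return object of class `tet_mesh` with fields `nodes`, `tets`,
#'   `facets` (f x 3, outward), `facet_tag` (integer, `NA` until
#'   [tag_boundaries()] is applied), `vol` (per-element volumes, um^3),
#'   `V_omega` (total fluid volume, um^3), `h`, `box`, `metadata`.
#' @export
tet_mesh <- function(nodes, tets, h = NULL, box = NULL, metadata = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  if (min(tets) < 1L || max(tets) > nrow(nodes)) stop("tet indices out of range")

  sv <- signed_volumes(nodes, tets)
  neg <- sv < 0
  if (any(neg)) {   # fix orientation by swapping the last two vertices
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
    sv[neg] <- -sv[neg]
  }
  if (any(sv <= 0)) stop("degenerate tetrahedron with zero volume")

  bf <- boundary_facets(tets)
  m <- list(nodes = nodes, tets = tets, facets = bf,
            facet_tag = rep(NA_integer_, nrow(bf)),
            vol = sv, V_omega = sum(sv),
            h = h, box = box, metadata = metadata)
  class(m) <- "tet_mesh"
  m
}

## signed volume of each tetrahedron, vectorized
signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

## outward-oriented boundary triangles: faces used by exactly one tet.
## For a positively oriented tet (a,b,c,d) the outward faces are
## (a,c,b), (a,b,d), (a,d,c), (b,c,d).
boundary_facets <- function(tets) {
  a <- tets[, 1]; b <- tets[, 2]; c <- tets[, 3]; d <- tets[, 4]
  faces <- rbind(cbind(a, c, b), cbind(a, b, d), cbind(a, d, c), cbind(b, c, d))
  key <- face_key(faces)
  cnt <- tabulate(match(key, unique(key)))[match(key, unique(key))]
  if (any(cnt > 2L)) stop("internal error: face shared by more than two tets")
  faces[cnt == 1L, , drop = FALSE]
}

face_key <- function(faces) {
  s <- cbind(pmin(faces[, 1], faces[, 2], faces[, 3]),
             pmax(faces[, 1], faces[, 2], faces[, 3]))
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - s[, 1] - s[, 2]
  paste(s[, 1], mid, s[, 2])
}

#' Areas of boundary facets
#' @param mesh a `tet_mesh`.
#' @return numeric vector of triangle areas (um^2), one per boundary facet.
#' @export
facet_areas <- function(mesh) {
  p1 <- mesh$nodes[mesh$facets[, 1], , drop = FALSE]
  u <- mesh$nodes[mesh$facets[, 2], , drop = FALSE] - p1
  v <- mesh$nodes[mesh$facets[, 3], , drop = FALSE] - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Tag boundary facets as inlet, outlet or solid interface
#'
#' Facets whose three nodes lie on one of the named box planes are tagged
#' inlet or outlet; every remaining boundary facet is the scaffold-fluid
#' interface (solid, Robin condition). The default follows the convention
#' that flow enters through the three minimum-coordinate faces and leaves
#' through the three maximum-coordinate faces; pass single planes (e.g.
#' `inlet = "xmin"`) for axis-aligned duct problems.
#'
#' @param mesh a `tet_mesh`.
#' @param box the [box_spec()] that bounds the mesh.
#' @param inlet,outlet character vectors drawn from
#'   `c("xmin","xmax","ymin","ymax","zmin","zmax")`; must be disjoint.
#' @param tol plane-membership tolerance (um), default `1e-6 * h`.
#' @return the mesh with `facet_tag` filled in (1 inlet, 2 outlet, 3 solid).
#' @export
tag_boundaries <- function(mesh, box,
                           inlet = c("xmin", "ymin", "zmin"),
                           outlet = c("xmax", "ymax", "zmax"),
                           tol = NULL) {
  planes <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
  inlet <- match.arg(inlet, planes, several.ok = TRUE)
  outlet <- match.arg(outlet, planes, several.ok = TRUE)
  if (length(intersect(inlet, outlet)))
    stop("inlet and outlet plane sets must be disjoint")
  if (is.null(tol)) tol <- 1e-6 * (if (is.null(mesh$h)) 1 else mesh$h)

  on_plane <- function(plane) {
    ax <- match(substr(plane, 1, 1), c("x", "y", "z"))
    ref <- if (endsWith(plane, "min")) 0 else box$L[ax]
    co <- matrix(mesh$nodes[mesh$facets, ax], ncol = 3L)
    rowSums(abs(co - ref) < tol) == 3L
  }

  tag <- rep(SOLID, nrow(mesh$facets))
  for (p in outlet) tag[on_plane(p)] <- OUTLET
  for (p in inlet) tag[on_plane(p)] <- INLET
  mesh$facet_tag <- tag
  mesh$metadata$inlet_planes <- inlet
  mesh$metadata$outlet_planes <- outlet
  mesh
}

#' Total boundary area per tag
#' @param mesh a tagged `tet_mesh`.
#' @return named numeric vector with areas (um^2) of inlet, outlet, solid.
#' @export
boundary_areas <- function(mesh) {
  if (anyNA(mesh$facet_tag)) stop("mesh boundary is untagged; run tag_boundaries()")
  ar <- facet_areas(mesh)
  vapply(1:3, function(t) sum(ar[mesh$facet_tag == t]), numeric(1)) |>
    stats::setNames(.tag_names)
}

#' Nodes lying on tagged boundary facets
#' @param mesh a tagged `tet_mesh`.
#' @param tag one of `"inlet"`, `"outlet"`, `"solid"`.
#' @return sorted integer vector of node indices.
#' @export
boundary_nodes <- function(mesh, tag = "inlet") {
  t <- match(match.arg(tag, .tag_names), .tag_names)
  sort(unique(as.vector(mesh$facets[mesh$facet_tag == t, ])))
}

#' Fingerprint of a mesh (for cache keying)
#'
#' MD5 of the serialized node and connectivity arrays; two meshes with
#' identical nodes/tets/tags share a fingerprint.
#' @param mesh a `tet_mesh`.
#' @return character scalar.
#' @export
mesh_fingerprint <- function(mesh) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(round(mesh$nodes, 9), mesh$tets, mesh$facet_tag), f,
          compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary facets, V = %.4g um^3\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$facets), x$V_omega))
  if (!anyNA(x$facet_tag))
    cat(sprintf("  tags: %d inlet, %d outlet, %d solid\n",
                sum(x$facet_tag == INLET), sum(x$facet_tag == OUTLET),
                sum(x$facet_tag == SOLID)))
  if (!is.null(x$metadata$porosity))
    cat(sprintf("  porosity %.3f (%s)\n", x$metadata$porosity,
                x$metadata$generator %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
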