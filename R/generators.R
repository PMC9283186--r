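## Synthetic scaffold geometry generators. Real scaffold domains in this
## field come from micro-CT segmentation; these voxel-based stand-ins
## emulate the two canonical architectures (foamed: overlapping spherical
## pores; 3D-printed: orthogonal grid of rectilinear strands) so that the
## transport and ROM pipeline is testable without imaging data.

#' 3D-printed (structured) scaffold specification
#'
#' Orthogonal woodpile of cylindrical strands laid in alternating X- and
#' Y-direction layers, with vertical layer pitch equal to the strand
#' diameter. The defaults target the printed-scaffold morphology used as a
#' reference in this package: porosity about 0.54 with pores of a few
#' hundred micrometres (nominal porosity of the continuous geometry is
#' `1 - pi * diameter / (4 * spacing)`).
#'
#' @param diameter strand diameter (um).
#' @param spacing centre-to-centre strand spacing within a layer (um).
#' @param offset_scheme `"aligned"` (strands of parallel layers stacked) or
#'   `"staggered"` (every second parallel layer shifted by spacing/2).
#' @param target_porosity intended fluid fraction, in (0, 1); recorded in
#'   metadata and compared against the achieved voxel porosity.
#' @return object of class `structured_spec`.
#' @export
structured_spec <- function(diameter = 350, spacing = 600,
                            offset_scheme = c("aligned", "staggered"),
                            target_porosity = 0.541) {
  offset_scheme <- match.arg(offset_scheme)
  if (diameter <= 0) stop("strand diameter must be positive")
  if (diameter >= spacing)
    stop("strands overlap fully: strand diameter must be smaller than spacing")
  if (target_porosity <= 0 || target_porosity >= 1)
    stop("target_porosity must be in (0, 1)")
  structure(list(diameter = diameter, spacing = spacing,
                 offset_scheme = offset_scheme,
                 target_porosity = target_porosity),
            class = "structured_spec")
}

#' Foamed scaffold specification
#'
#' Pore space modelled as the union of randomly placed overlapping spheres
#' with lognormal radii, clipped to the box and reduced to the largest
#' face-connected component. Defaults target the foamed-scaffold
#' morphology used as a reference in this package: porosity about 0.52,
#' mean pore diameter about 227 um.
#'
#' @param median_radius median sphere radius (um).
#' @param shape lognormal shape parameter (sdlog) of the radius law.
#' @param target_porosity intended fluid fraction, in (0, 1).
#' @param seed integer random seed; recorded in the mesh metadata.
#' @return object of class `foamed_spec`.
#' @export
foamed_spec <- function(median_radius = 113.5, shape = 0.25,
                        target_porosity = 0.523, seed = 1L) {
  if (median_radius <= 0) stop("median_radius must be positive")
  if (target_porosity <= 0 || target_porosity >= 1)
    stop("target_porosity must be in (0, 1)")
  if (is.null(seed)) stop("a random seed is required for reproducibility")
  structure(list(median_radius = median_radius, shape = shape,
                 target_porosity = target_porosity, seed = as.integer(seed)),
            class = "foamed_spec")
}

#' Generate the fluid domain of a 3D-printed scaffold
#'
#' Builds the voxel mask of the box minus the strand grid, keeps the
#' largest face-connected fluid component, meshes it with
#' [voxel_to_tets()] and tags the boundary (min-faces inlet, max-faces
#' outlet, strand surfaces solid). Deterministic.
#'
#' @param box a [box_spec()].
#' @param spec a [structured_spec()].
#' @param inlet,outlet plane sets passed to [tag_boundaries()].
#' @return a tagged `tet_mesh`; `metadata$porosity` holds the achieved
#'   voxel porosity (fluid voxels / total voxels).
#' @export
generate_structured <- function(box, spec = structured_spec(),
                                inlet = c("xmin", "ymin", "zmin"),
                                outlet = c("xmax", "ymax", "zmax")) {
  vc <- voxel_centers(box)
  d2 <- (spec$diameter / 2)^2
  pitch <- spec$diameter           # vertical pitch: one strand diameter
  solid <- array(FALSE, box$n)

  layer <- floor(vc$z / pitch)     # layer index per z-slab
  zc_layer <- (layer + 0.5) * pitch
  for (k in seq_along(vc$z)) {
    L <- layer[k]
    along_x <- (L %% 2 == 0)
    off <- if (spec$offset_scheme == "staggered" && (L %/% 2) %% 2 == 1)
      spec$spacing / 2 else 0
    perp <- if (along_x) vc$y else vc$x   # coordinate across the strands
    ax <- (perp - off) %% spec$spacing    # distance to nearest axis, wrapped
    dist2 <- pmin(ax, spec$spacing - ax)^2 + (vc$z[k] - zc_layer[k])^2
    hit <- dist2 < d2
    if (along_x) solid[, hit, k] <- TRUE else solid[hit, , k] <- TRUE
  }

  fluid <- !solid
  if (!any(fluid))
    stop("fluid domain empty: decrease strand diameter or increase spacing")
  lc <- largest_component(fluid)
  if (lc$n_components > 1L)
    warning("fluid domain had ", lc$n_components,
            " components; keeping the largest")
  porosity <- sum(lc$mask) / length(lc$mask)

  mesh <- voxel_to_tets(lc$mask, box)
  mesh <- tag_boundaries(mesh, box, inlet = inlet, outlet = outlet)
  mesh$metadata <- c(mesh$metadata,
                     list(generator = "structured", spec = unclass(spec),
                          porosity = porosity,
                          nominal_porosity = 1 - pi * spec$diameter /
                            (4 * spec$spacing)))
  mesh
}

#' Generate the fluid domain of a foamed scaffold
#'
#' Inserts spheres with lognormal radii at uniform random centres until
#' the voxel fluid fraction reaches the target (or an insertion cap),
#' keeps the largest face-connected component, meshes and tags it. The
#' same seed reproduces the mesh bit-for-bit.
#'
#' @param box a [box_spec()].
#' @param spec a [foamed_spec()].
#' @param max_spheres insertion cap before giving up on the target.
#' @param inlet,outlet plane sets passed to [tag_boundaries()].
#' @return a tagged `tet_mesh`; `metadata$porosity` is the achieved
#'   porosity (largest-component voxels / total voxels), `metadata$seed`
#'   and `metadata$n_spheres` record provenance.
#' @export
generate_foamed <- function(box, spec = foamed_spec(), max_spheres = 10000L,
                            inlet = c("xmin", "ymin", "zmin"),
                            outlet = c("xmax", "ymax", "zmax")) {
  vc <- voxel_centers(box)
  fluid <- array(FALSE, box$n)
  n_tot <- length(fluid)
  set.seed(spec$seed)

  n_sph <- 0L
  while (sum(fluid) / n_tot < spec$target_porosity) {
    if (n_sph >= max_spheres)
      stop(sprintf(paste0("porosity target %.3f unreachable after %d spheres ",
                          "(achieved %.3f); increase median_radius or the cap"),
                   spec$target_porosity, max_spheres, sum(fluid) / n_tot))
    ctr <- stats::runif(3) * box$L
    r <- stats::rlnorm(1, meanlog = log(spec$median_radius),
                       sdlog = spec$shape)
    ix <- which(abs(vc$x - ctr[1]) <= r)
    iy <- which(abs(vc$y - ctr[2]) <= r)
    iz <- which(abs(vc$z - ctr[3]) <= r)
    if (length(ix) && length(iy) && length(iz)) {
      dx2 <- (vc$x[ix] - ctr[1])^2
      dy2 <- (vc$y[iy] - ctr[2])^2
      dz2 <- (vc$z[iz] - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      fluid[ix, iy, iz] <- fluid[ix, iy, iz, drop = FALSE] | (d2 <= r^2)
    }
    n_sph <- n_sph + 1L
  }

  lc <- largest_component(fluid)
  porosity <- sum(lc$mask) / n_tot
  mesh <- voxel_to_tets(lc$mask, box)
  mesh <- tag_boundaries(mesh, box, inlet = inlet, outlet = outlet)
  mesh$metadata <- c(mesh$metadata,
                     list(generator = "foamed", spec = unclass(spec),
                          porosity = porosity, seed = spec$seed,
                          n_spheres = n_sph,
                          n_components = lc$n_components))
  mesh
}
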