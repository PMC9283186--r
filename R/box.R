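#' Axis-aligned box specification
#'
#' Defines the bounding box of a scaffold fluid domain together with the
#' voxel resolution used by the synthetic geometry generators. All lengths
#' are in micrometres. Each side length must be an integer multiple of the
#' voxel size `h`, so that the box maps exactly onto a voxel lattice.
#'
#' @param Lx,Ly,Lz side lengths of the box (um), all > 0.
#' @param h voxel edge length (um), > 0; must divide each side length.
#' @return an object of class `box_spec` with fields `L` (lengths),
#'   `h`, and `n` (integer voxel counts per axis).
#' @examples
#' box_spec(200, 100, 100, h = 25)
#' @export
box_spec <- function(Lx, Ly, Lz, h) {
  L <- c(Lx, Ly, Lz)
  if (any(!is.finite(L)) || any(L <= 0)) stop("box lengths must be positive")
  if (!is.finite(h) || h <= 0) stop("voxel size h must be positive")
  n <- L / h
  if (any(abs(n - round(n)) > 1e-9))
    stop("each box length must be an integer multiple of h")
  structure(list(L = L, h = h, n = as.integer(round(n))),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("box %g x %g x %g um, h = %g um (%d x %d x %d voxels)\n",
              x$L[1], x$L[2], x$L[3], x$h, x$n[1], x$n[2], x$n[3]))
  invisible(x)
}

#' Voxel centre coordinates of a box lattice
#'
#' @param box a [box_spec()].
#' @return list of three vectors `x`, `y`, `z` with voxel-centre coordinates.
#' @keywords internal
voxel_centers <- function(box) {
  list(x = (seq_len(box$n[1]) - 0.5) * box$h,
       y = (seq_len(box$n[2]) - 0.5) * box$h,
       z = (seq_len(box$n[3]) - 0.5) * box$h)
}
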