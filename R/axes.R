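#' Long axis of a surface grid
#'
#' The long axis runs from the centroid of the most basal ring to the most
#' apical point: the grid point farthest from the basal plane along the
#' base-to-apex direction (ties broken by lowest circumferential index).  The
#' base-to-apex direction is taken as the unit vector from the basal-ring
#' centroid to the apical-ring centroid.
#'
#' @param grid a [surface_grid()].
#' @return List of class `long_axis` with `basal_centroid`, `apex_point`,
#'   `length` (mm) and `direction` (unit base-to-apex vector).
#' @export
long_axis <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  pts <- grid$points
  base_c <- colMeans(pts[ring_rows(grid, 0L), , drop = FALSE])
  apex_ring_c <- colMeans(pts[ring_rows(grid, grid$R - 1L), , drop = FALSE])
  d <- apex_ring_c - base_c
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9)
    stop("cannot orient long axis: apical ring centroid coincides with basal centroid")
  d <- d / nd
  h <- as.numeric((pts - matrix(base_c, nrow(pts), 3, byrow = TRUE)) %*% d)
  if (max(h) < 1e-9)
    stop("all points are coplanar with the basal ring; no apex")
  apex_i <- which(h == max(h))[1L]  # ring-major order => lowest circ index wins
  apex <- pts[apex_i, ]
  structure(list(basal_centroid = base_c, apex_point = apex,
                 length = sqrt(sum((apex - base_c)^2)), direction = d),
            class = "long_axis")
}

#' @export
print.long_axis <- function(x, ...) {
  cat(sprintf("<long_axis> length %.2f mm\n", x$length))
  invisible(x)
}

#' Diameter of one grid ring
#'
#' Defined as twice the mean distance of the ring's points from the ring
#' centroid (exact for a circular ring, robust to grid anisotropy).
#'
#' @param grid a [surface_grid()].
#' @param ring 0-based ring index (`0` = most basal).
#' @return Diameter in mm.
#' @export
ring_diameter <- function(grid, ring) {
  stopifnot(inherits(grid, "surface_grid"))
  pts <- grid$points[ring_rows(grid, as.integer(ring)), , drop = FALSE]
  ctr <- colMeans(pts)
  2 * mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
}
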