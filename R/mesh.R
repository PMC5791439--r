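#' Close a surface grid into a triangle mesh
#'
#' Splits each grid quad into two triangles and adds a basal cap (triangle fan
#' from the basal-ring centroid) and an apical cap (fan from the apical-ring
#' centroid), producing a closed, consistently outward-oriented surface on
#' which enclosed volumes are well defined.
#'
#' @param grid a [surface_grid()].
#' @return A `triangle_mesh`: list with `vertices` ((R*C + 2) x 3 matrix, the
#'   two cap centroids appended last) and `faces` (integer matrix, one
#'   consistently wound triangle per row; `2*(R-1)*C + 2*C` faces).
#' @details A degenerate cap (ring collapsed onto its centroid) triggers a
#'   warning; the mesh is still returned.
#' @export
close_surface <- function(grid) {
  stopifnot(inherits(grid, "surface_grid"))
  R <- grid$R; C <- grid$C
  pts <- grid$points
  base_rows <- ring_rows(grid, 0L)
  apex_rows <- ring_rows(grid, R - 1L)
  base_c <- colMeans(pts[base_rows, , drop = FALSE])
  apex_c <- colMeans(pts[apex_rows, , drop = FALSE])
  for (nm in c("base", "apex")) {
    rows <- if (nm == "base") base_rows else apex_rows
    ctr <- if (nm == "base") base_c else apex_c
    rad <- sqrt(rowSums((pts[rows, , drop = FALSE] -
                           matrix(ctr, C, 3, byrow = TRUE))^2))
    if (max(rad) < 1e-9)
      warning(sprintf("degenerate %s cap: ring coincides with its centroid", nm))
  }
  vertices <- rbind(pts, base = base_c, apex = apex_c)
  vb <- R * C + 1L   # basal centroid index
  va <- R * C + 2L   # apical centroid index

  idx <- function(j, k) j * C + (k %% C) + 1L  # j, k 0-based -> vertex row
  j <- rep(0:(R - 2L), each = C)
  k <- rep(0:(C - 1L), times = R - 1L)
  a <- idx(j, k); b <- idx(j, k + 1L)
  cc <- idx(j + 1L, k + 1L); d <- idx(j + 1L, k)
  wall <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  k0 <- 0:(C - 1L)
  cap_base <- cbind(vb, idx(0L, k0 + 1L), idx(0L, k0))
  cap_apex <- cbind(va, idx(R - 1L, k0), idx(R - 1L, k0 + 1L))
  faces <- rbind(wall, cap_base, cap_apex)
  colnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  # pin global orientation outward (positive signed volume)
  if (signed_mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# signed volume in mm^3 (divergence theorem over triangles)
signed_mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  # translate to the first vertex so the sum is exactly translation-invariant
  o <- p1[1, ]
  p1 <- sweep(p1, 2, o); p2 <- sweep(p2, 2, o); p3 <- sweep(p3, 2, o)
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6
}

# undirected edge multiplicities; integer-encoded for speed
mesh_edge_check <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- (pmin(e[, 1], e[, 2]) - 1) * nv + pmax(e[, 1], e[, 2])
  r <- rle(sort(key))
  v2 <- (r$values - 1) %% nv + 1
  v1 <- (r$values - v2) / nv + 1
  list(count = r$lengths, v1 = v1, v2 = v2)
}

#' Is a mesh a closed edge-manifold surface?
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` if every undirected edge is shared by exactly two faces.
#' @export
is_closed_mesh <- function(mesh) {
  all(mesh_edge_check(mesh)$count == 2L)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Sum of signed tetrahedron volumes `det(v1, v2, v3) / 6` over faces
#' (absolute value), converted from cubic millimetres to millilitres.
#' Translation- and rotation-invariant for closed, consistently oriented
#' surfaces.
#'
#' @param mesh a closed `triangle_mesh` with coordinates in mm.
#' @return Volume in ml.
#' @export
surface_volume <- function(mesh) {
  ec <- mesh_edge_check(mesh)
  bad <- which(ec$count != 2L)
  if (length(bad))
    stop("mesh is not closed; unmatched edges: ",
         paste(sprintf("%d-%d", ec$v1[utils::head(bad, 5L)],
                       ec$v2[utils::head(bad, 5L)]), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  abs(signed_mesh_volume(mesh)) / 1000
}
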