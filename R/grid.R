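#' Surface point grid
#'
#' An ordered ring-by-circumference lattice of 3D points sampling one cardiac
#' surface (endocardium or epicardium) at one frame (end-diastole or
#' end-systole).  Ring 0 is the most basal ring, ring `R - 1` the most apical.
#' Coordinates are in millimetres.
#'
#' @param points numeric matrix with `R * C` rows and 3 columns (x, y, z, mm),
#'   in ring-major order: all circumferential points of ring 0 first, then
#'   ring 1, and so on.
#' @param R number of rings (>= 4).
#' @param C number of circumferential points per ring (>= 3).
#' @param surface `"endo"` or `"epi"`.
#' @param frame `"ED"` or `"ES"`.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(points, R, C, surface = c("endo", "epi"),
                         frame = c("ED", "ES")) {
  surface <- match.arg(surface)
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("'points' must be a numeric matrix with 3 columns")
  R <- as.integer(R); C <- as.integer(C)
  if (R < 4L || C < 3L)
    stop("grid requires R >= 4 rings and C >= 3 circumferential points")
  if (nrow(points) != R * C)
    stop(sprintf("expected %d points (R*C), got %d", R * C, nrow(points)))
  if (!all(is.finite(points)))
    stop("all grid points must be finite")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, R = R, C = C,
                 surface = surface, frame = frame),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %s @ %s, %d rings x %d points (mm)\n",
              x$surface, x$frame, x$R, x$C))
  invisible(x)
}

# row indices of ring j (0-based) in the ring-major point matrix
ring_rows <- function(grid, ring) {
  if (ring < 0L || ring >= grid$R) stop("ring index out of bounds")
  ring * grid$C + seq_len(grid$C)
}

#' Per-subject left-ventricular shape model
#'
#' Bundles the four surface grids of one subject: endocardium and epicardium
#' at end-diastole and end-systole, all on the same ring-by-circumference
#' lattice (homologous correspondence across the cohort).
#'
#' @param ed_endo,ed_epi,es_endo,es_epi [surface_grid()] objects with matching
#'   dimensions and the corresponding `surface`/`frame` tags.
#' @param subject_id optional subject identifier.
#' @return An object of class `shape_model`.
#' @export
shape_model <- function(ed_endo, ed_epi, es_endo, es_epi, subject_id = NA) {
  grids <- list(ed_endo = ed_endo, ed_epi = ed_epi,
                es_endo = es_endo, es_epi = es_epi)
  want <- list(ed_endo = c("endo", "ED"), ed_epi = c("epi", "ED"),
               es_endo = c("endo", "ES"), es_epi = c("epi", "ES"))
  R <- ed_endo$R; C <- ed_endo$C
  for (nm in names(grids)) {
    g <- grids[[nm]]
    if (!inherits(g, "surface_grid")) stop(nm, " is not a surface_grid")
    if (g$R != R || g$C != C)
      stop("all four grids must share the same R x C dimensions")
    if (g$surface != want[[nm]][1] || g$frame != want[[nm]][2])
      stop(sprintf("grid '%s' is tagged %s/%s, expected %s/%s",
                   nm, g$surface, g$frame, want[[nm]][1], want[[nm]][2]))
  }
  structure(c(grids, list(R = R, C = C, subject_id = subject_id)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> subject %s, grids %d x %d, P = %d\n",
              as.character(x$subject_id), x$R, x$C, 4L * x$R * x$C * 3L))
  invisible(x)
}

#' Flatten a shape model into a shape vector
#'
#' Deterministic concatenation used to build rows of the cohort shape matrix:
#' frame ED then ES, surface endo then epi within each frame, points in
#' ring-major order, and x, y, z per point.  The mapping is a bijection;
#' [unflatten_model()] inverts it exactly.
#'
#' @param model a [shape_model()].
#' @param R,C expected cohort grid dimensions; defaults to the model's own.
#' @return Numeric vector of length `P = 2 * 2 * R * C * 3`.
#' @export
flatten_model <- function(model, R = model$R, C = model$C) {
  if (model$R != R || model$C != C)
    stop(sprintf("model grid %dx%d does not match cohort convention %dx%d",
                 model$R, model$C, R, C))
  c(t(model$ed_endo$points), t(model$ed_epi$points),
    t(model$es_endo$points), t(model$es_epi$points))
}

#' Rebuild a shape model from a flattened shape vector
#'
#' @param v numeric vector of length `2 * 2 * R * C * 3` in the
#'   [flatten_model()] ordering.
#' @param R,C grid dimensions.
#' @param subject_id optional identifier for the rebuilt model.
#' @return A [shape_model()].
#' @export
unflatten_model <- function(v, R, C, subject_id = NA) {
  n <- R * C * 3L
  if (length(v) != 4L * n)
    stop(sprintf("vector length %d does not match 4*R*C*3 = %d",
                 length(v), 4L * n))
  take <- function(i) matrix(v[((i - 1L) * n + 1L):(i * n)],
                             ncol = 3L, byrow = TRUE)
  shape_model(
    surface_grid(take(1L), R, C, "endo", "ED"),
    surface_grid(take(2L), R, C, "epi", "ED"),
    surface_grid(take(3L), R, C, "endo", "ES"),
    surface_grid(take(4L), R, C, "epi", "ES"),
    subject_id = subject_id)
}
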