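#' Body surface area (Mosteller)
#'
#' `sqrt(height * weight / 3600)` with height in cm and weight in kg.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return BSA in square metres.
#' @export
body_surface_area <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Left-ventricular mass from surface volumes
#'
#' Myocardial volume (epicardial minus endocardial surface volume) times the
#' myocardial density 1.05 g/ml.
#'
#' @param epi_vol,endo_vol volumes in ml, `epi_vol >= endo_vol >= 0`.
#' @return Mass in grams.
#' @export
lv_mass <- function(epi_vol, endo_vol) {
  if (any(endo_vol < 0)) stop("volumes must be non-negative")
  if (any(epi_vol < endo_vol))
    stop("epicardial volume smaller than endocardial volume (surfaces crossed)")
  (epi_vol - endo_vol) * 1.05
}

#' Ejection fraction
#'
#' `(EDV - ESV) / EDV` from endocardial cavity volumes.
#'
#' @param edv end-diastolic volume (ml, > 0).
#' @param esv end-systolic volume (ml).
#' @return Fraction (0-1 when `esv <= edv`).
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("EDV must be positive")
  (edv - esv) / edv
}

# mid-ventricular ring index, 0-based
mid_ring <- function(R) (R - 1L) %/% 2L

# circumferential indices of the posterior sector: the quarter of the ring
# centered on the -y template direction (k = 3C/4 with k = 0 at +x)
posterior_sector <- function(C) {
  half <- max(1L, C %/% 8L)
  (round(3 * C / 4) + (-half:half)) %% C
}

#' Relative wall thickness
#'
#' Twice the posterior wall thickness divided by the end-diastolic diameter at
#' mid-ventricle.  Wall thickness is the mean endocardium-to-epicardium
#' point distance over the posterior quarter of the mid-ventricular ring at
#' end-diastole; the diameter is the endocardial [ring_diameter()] of the same
#' ring.
#'
#' @param model a [shape_model()].
#' @return RWT as a fraction.
#' @export
relative_wall_thickness <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  m <- mid_ring(model$R)
  rows <- m * model$C + posterior_sector(model$C) + 1L
  d <- model$ed_epi$points[rows, , drop = FALSE] -
    model$ed_endo$points[rows, , drop = FALSE]
  thickness <- mean(sqrt(rowSums(d^2)))
  diam <- ring_diameter(model$ed_endo, m)
  if (diam <= 1e-9) stop("zero mid-ventricular diameter")
  2 * thickness / diam
}

#' Sphericity
#'
#' End-diastolic volume divided by the volume of a sphere whose diameter is
#' the end-diastolic endocardial long-axis length.
#'
#' @param model a [shape_model()].
#' @param edv optional precomputed ED endocardial volume (ml); computed from
#'   the closed mesh when missing.
#' @return Sphericity fraction.
#' @export
sphericity <- function(model, edv = NULL) {
  stopifnot(inherits(model, "shape_model"))
  if (is.null(edv)) edv <- surface_volume(close_surface(model$ed_endo))
  L <- long_axis(model$ed_endo)$length
  if (L <= 1e-9) stop("zero-length long axis")
  sphere_ml <- pi / 6 * L^3 / 1000  # L in mm -> mm^3 -> ml
  edv / sphere_ml
}

#' Apical conicity
#'
#' Ratio of the apical diameter (endocardial diameter one-third of the
#' long-axis length above the apex) over the basal diameter, both at
#' end-diastole.  The apical ring is the one whose centroid's distance from
#' the apex along the long-axis direction is nearest to `L/3` (selection by
#' arc position, robust to nonuniform ring spacing).
#'
#' @param model a [shape_model()].
#' @return Conicity fraction.
#' @export
conicity <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  g <- model$ed_endo
  ax <- long_axis(g)
  basal_d <- ring_diameter(g, 0L)
  if (basal_d <= 1e-9) stop("zero basal diameter")
  # distance of each ring centroid from the apex, measured along the axis
  ctrs <- t(vapply(0:(g$R - 1L), function(j)
    colMeans(g$points[ring_rows(g, j), , drop = FALSE]), numeric(3)))
  h_apex <- sum((ax$apex_point - ax$basal_centroid) * ax$direction)
  h <- as.numeric((ctrs - matrix(ax$basal_centroid, g$R, 3, byrow = TRUE)) %*%
                    ax$direction)
  dist_from_apex <- h_apex - h
  j_third <- which.min(abs(dist_from_apex - ax$length / 3)) - 1L
  ring_diameter(g, j_third) / basal_d
}

#' Longitudinal shortening
#'
#' Fractional systolic shortening of the endocardial long axis:
#' `(L_ED - L_ES) / L_ED`.
#'
#' @param model a [shape_model()].
#' @return Fraction.
#' @export
longitudinal_shortening <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  l_ed <- long_axis(model$ed_endo)$length
  if (l_ed <= 1e-9) stop("zero end-diastolic long-axis length")
  l_es <- long_axis(model$es_endo)$length
  (l_ed - l_es) / l_ed
}

#' All clinical remodeling indices for one subject
#'
#' Computes cavity volumes by closed-surface triangle summation and derives
#' the six remodeling indices: EDVI, sphericity, EF, RWT, conicity and
#' longitudinal shortening, plus LV mass and BSA.
#'
#' @param model a [shape_model()].
#' @param height_cm,weight_kg subject height (cm) and weight (kg) for BSA.
#' @return A one-row `data.frame` with columns `subject_id, edv, esv, mass,
#'   bsa, edvi, ef, rwt, sphericity, conicity, ls` (volumes ml, mass g, BSA
#'   m^2, EDVI ml/m^2, the rest fractions).
#' @export
compute_indices <- function(model, height_cm, weight_kg) {
  stopifnot(inherits(model, "shape_model"))
  res <- tryCatch({
    edv <- surface_volume(close_surface(model$ed_endo))
    esv <- surface_volume(close_surface(model$es_endo))
    epi_ed <- surface_volume(close_surface(model$ed_epi))
    bsa <- body_surface_area(height_cm, weight_kg)
    data.frame(
      subject_id = as.character(model$subject_id),
      edv = edv, esv = esv,
      mass = lv_mass(epi_ed, edv),
      bsa = bsa,
      edvi = edv / bsa,
      ef = ejection_fraction(edv, esv),
      rwt = relative_wall_thickness(model),
      sphericity = sphericity(model, edv = edv),
      conicity = conicity(model),
      ls = longitudinal_shortening(model),
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop(sprintf("subject %s: %s", as.character(model$subject_id),
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Clinical indices for a list of shape models
#'
#' @param models list of [shape_model()] objects.
#' @param height_cm,weight_kg vectors aligned with `models`.
#' @return A `data.frame`, one row per subject, as in [compute_indices()].
#' @export
compute_indices_cohort <- function(models, height_cm, weight_kg) {
  stopifnot(length(models) == length(height_cm),
            length(models) == length(weight_kg))
  do.call(rbind, lapply(seq_along(models), function(i)
    compute_indices(models[[i]], height_cm[i], weight_kg[i])))
}
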