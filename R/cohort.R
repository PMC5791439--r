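# run code with a local RNG stream, restoring the caller's .Random.seed
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cross-section integral of the superellipse profile: V = pi * rb^2 * L * I(p)
profile_integral <- function(p, umax) {
  stats::integrate(function(u) (1 - u^p)^(2 / p), 0, umax,
                   rel.tol = 1e-10)$value
}

# analytic apical-to-basal diameter ratio of the continuous profile (used by
# the calibration secant updates, not by the index pipeline)
profile_conicity <- function(p) (1 - (2 / 3)^p)^(1 / p)

#' Calibration targets: reference cohort index means and SDs
#'
#' Group means and standard deviations of the six remodeling indices, plus
#' demographics, for the reference asymptomatic and myocardial-infarction
#' cohorts that the synthetic generator is calibrated to emulate.
#'
#' @return Nested list with `asymp` and `mi` entries (`mean`/`sd` per index,
#'   fractions throughout; EDVI in ml/m^2) and covariate distributions.
#' @export
reference_targets <- function() {
  list(
    asymp = list(
      mean = c(edvi = 67.83, sphericity = 0.38, rwt = 0.3971,
               conicity = 0.74, ef = 0.63, ls = 0.13),
      sd = c(edvi = 13.29, sphericity = 0.08, rwt = 0.0949,
             conicity = 0.08, ef = 0.07, ls = 0.04),
      covariates = list(age_mean = 61.47, age_sd = 10.15, p_female = 1034 / 2009,
                        height_mean = 165.98, height_sd = 9.99,
                        weight_mean = 76.75, weight_sd = 16.50,
                        dbp_mean = 71.49, dbp_sd = 10.33,
                        p_smoking = 0.1251, p_diabetes = 0.1311)),
    mi = list(
      mean = c(edvi = 96.53, sphericity = 0.41, rwt = 0.3521,
               conicity = 0.70, ef = 0.41, ls = 0.08),
      sd = c(edvi = 25.03, sphericity = 0.09, rwt = 0.0838,
             conicity = 0.08, ef = 0.11, ls = 0.03),
      covariates = list(age_mean = 62.76, age_sd = 10.76, p_female = 60 / 298,
                        height_mean = 173.82, height_sd = 9.77,
                        weight_mean = 90.06, weight_sd = 14.14,
                        dbp_mean = 73.26, dbp_sd = 9.82,
                        p_smoking = 0.1133, p_diabetes = 0.3567)))
}

#' Synthetic-cohort generator configuration
#'
#' Defaults are the shipped calibration: template parameters, latent effect
#' loadings and MI latent shifts were set once by [calibrate_generator()]
#' (coordinate search matching the [reference_targets()] index means and the
#' asymptomatic SDs through the full index pipeline) and are frozen here.
#'
#' The six latents (unit-variance Gaussians) each drive one index:
#' size (EDVI), sphericity, wall thickness (RWT), taper (conicity), radial
#' contraction (EF) and longitudinal contraction (LS).  Size/sphericity/taper
#' modulations are volume-preserving where needed so that the size latent is
#' the only driver of cavity volume, making the generative directions
#' identifiable from shape data.
#'
#' @param n_asymp,n_mi group sizes (defaults: the reference cohort sizes).
#' @param R,C grid dimensions (29 x 29 x 2 surfaces = 1682 points per frame).
#' @param L0 template endocardial long-axis length at end-diastole (mm).
#' @param rho0 basal-radius-to-length ratio.
#' @param t0 wall thickness (mm).
#' @param p0 taper exponent of the superellipse profile (2 = ellipsoid).
#' @param lr0,lL0 end-systolic radial and longitudinal contraction factors,
#'   in (0, 1).
#' @param umax longitudinal truncation fraction of the profile.
#' @param loadings length-6 latent effect loadings (log/logit scale SDs).
#' @param mi_shift length-6 MI-group latent mean shifts.
#' @param noise_sd iid Gaussian point noise SD (mm).
#' @param seed integer seed; a fixed seed makes the cohort bitwise
#'   reproducible.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_asymp = 1991L, n_mi = 300L,
                             R = 29L, C = 29L,
                             L0 = 85.3294, rho0 = 0.308099, t0 = 8.7694,
                             p0 = 2.038167, lr0 = 0.650383, lL0 = 0.873502,
                             umax = 0.995,
                             loadings = c(size = 0.049214, sphericity = 0.034649,
                                          thickness = 0.232824, taper = 0.173885,
                                          radial = 0.281326, longitudinal = 0.354831),
                             mi_shift = c(size = 3.099783, sphericity = 0.311907,
                                          thickness = -0.393979, taper = -0.499244,
                                          radial = -3.300951, longitudinal = -1.523792),
                             noise_sd = 0.5, seed = 20260919L) {
  if (any(loadings < 0)) stop("loadings (latent SD scales) must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lr0 <= 0 || lr0 > 1 || lL0 <= 0 || lL0 > 1)
    stop("contraction factors must lie in (0, 1]")
  structure(list(n_asymp = as.integer(n_asymp), n_mi = as.integer(n_mi),
                 R = as.integer(R), C = as.integer(C),
                 L0 = L0, rho0 = rho0, t0 = t0, p0 = p0,
                 lr0 = lr0, lL0 = lL0, umax = umax,
                 loadings = loadings, mi_shift = mi_shift,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 targets = reference_targets()),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d asymptomatic + %d MI, grid %dx%d, noise %.2f mm, seed %d\n",
              x$n_asymp, x$n_mi, x$R, x$C, x$noise_sd, x$seed))
  invisible(x)
}

#' Template left-ventricular shape for given latent values
#'
#' Builds a noise-free [shape_model()] from the generator template: the ED
#' endocardium is a truncated superellipsoid shell (ring j at longitudinal
#' fraction `u_j`, `z = -L u_j`, radius `r(u) = r_b (1 - u^p)^(1/p)`), the
#' epicardium adds a radial/apical wall-thickness offset `t`, and the ES
#' frames apply radial and longitudinal contraction factors about the basal
#' plane.  The six latents modulate size, basal-radius ratio, thickness,
#' taper and the two contraction factors through exponential (positive
#' parameters) or logistic (contraction fractions) links; the sphericity and
#' taper modulations are compensated to leave the cavity volume unchanged.
#'
#' @param config a [generator_config()].
#' @param latents length-6 numeric latent vector (0 = template mean).
#' @param subject_id optional identifier.
#' @return A [shape_model()].
#' @export
template_shape <- function(config, latents = rep(0, 6), subject_id = NA) {
  stopifnot(inherits(config, "generator_config"), length(latents) == 6L)
  a <- config$loadings
  z <- as.numeric(latents)
  s <- exp(a[1] * z[1])
  rmul <- exp(a[2] * z[2])
  Lmul <- exp(-2 * a[2] * z[2])
  t <- config$t0 * s * exp(a[3] * z[3])
  if (t <= 0) stop("modulated wall thickness is non-positive")
  p <- config$p0 * exp(a[4] * z[4])
  # minus signs: the radial/longitudinal latents drive EF and LS positively
  # (stronger contraction = smaller factor = higher ejection/shortening).
  # The longitudinal latent is ES-volume-preserving: lr compensates so that
  # lr^2 * lL (hence EF) depends on the radial latent alone.
  lL <- stats::plogis(stats::qlogis(config$lL0) - a[6] * z[6])
  lr <- stats::plogis(stats::qlogis(config$lr0) - a[5] * z[5]) *
    sqrt(config$lL0 / lL)
  if (lr >= 1) stop("modulated radial contraction factor reached 1")
  # volume-preserving taper compensation: V = pi rb^2 L I(p) kept at I(p0)
  r_comp <- sqrt(profile_integral(config$p0, config$umax) /
                   profile_integral(p, config$umax))
  L <- config$L0 * s * Lmul
  rb <- config$rho0 * config$L0 * s * rmul * r_comp

  R <- config$R; C <- config$C
  u <- config$umax * (seq_len(R) - 1) / (R - 1)
  th <- 2 * pi * (seq_len(C) - 1) / C
  shell <- function(rbase, Lax) {
    r <- rbase * (1 - u^p)^(1 / p)
    cbind(x = rep(r, each = C) * cos(th),
          y = rep(r, each = C) * sin(th),
          z = rep(-Lax * u, each = C))
  }
  ed_endo <- shell(rb, L)
  ed_epi <- shell(rb + t, L + t)
  contract <- function(pts) cbind(pts[, 1] * lr, pts[, 2] * lr, pts[, 3] * lL)
  shape_model(
    surface_grid(ed_endo, R, C, "endo", "ED"),
    surface_grid(ed_epi, R, C, "epi", "ED"),
    surface_grid(contract(ed_endo), R, C, "endo", "ES"),
    surface_grid(contract(ed_epi), R, C, "epi", "ES"),
    subject_id = subject_id)
}

# draw one group's covariate table; sex coded 1 = male, 0 = female
draw_covariates <- function(n, cv, group, id_offset) {
  sex <- stats::rbinom(n, 1, 1 - cv$p_female)
  dh <- 12; dw <- 10  # male-female offsets preserving the group mean
  p_m <- 1 - cv$p_female
  h_res <- sqrt(max(cv$height_sd^2 - dh^2 * p_m * (1 - p_m), 1))
  w_res <- sqrt(max(cv$weight_sd^2 - dw^2 * p_m * (1 - p_m), 1))
  height <- cv$height_mean + dh * (sex - p_m) + stats::rnorm(n, 0, h_res)
  weight <- cv$weight_mean + dw * (sex - p_m) + stats::rnorm(n, 0, w_res)
  height <- pmax(height, 120); weight <- pmax(weight, 35)
  data.frame(
    subject_id = sprintf("%s%04d", if (group == 1) "mi" else "as",
                         id_offset + seq_len(n)),
    group = group,
    age = stats::rnorm(n, cv$age_mean, cv$age_sd),
    sex = sex,
    height = height, weight = weight,
    bmi = weight / (height / 100)^2,
    dbp = stats::rnorm(n, cv$dbp_mean, cv$dbp_sd),
    smoking = stats::rbinom(n, 1, cv$p_smoking),
    diabetes = stats::rbinom(n, 1, cv$p_diabetes),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic LV cohort with known ground truth
#'
#' Draws, per subject: a group label, covariates from the group's reference
#' distributions, a length-6 latent vector `N(shift_group, I)`, the template
#' shape for those latents, and iid Gaussian point noise.  Ground-truth
#' latents and the unit generative directions (finite-difference shape
#' derivatives at the population mean) are recorded for parameter-recovery
#' testing.
#'
#' @param config a [generator_config()].
#' @return Object of class `lv_cohort`: `models` (list of [shape_model()]),
#'   `covariates` (data.frame), `labels` (0 = asymptomatic, 1 = MI),
#'   `true_latents` (N x 6), `true_directions` (P x 6 unit columns named by
#'   the index each latent drives), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_asymp < 1L && config$n_mi < 1L)
    stop("at least one group must have subjects")
  tg <- config$targets
  with_local_seed(config$seed, {
    groups <- list()
    if (config$n_asymp >= 1L)
      groups$asymp <- list(n = config$n_asymp, shift = rep(0, 6),
                           cv = tg$asymp$covariates, label = 0L)
    if (config$n_mi >= 1L)
      groups$mi <- list(n = config$n_mi, shift = as.numeric(config$mi_shift),
                        cv = tg$mi$covariates, label = 1L)
    cov_list <- list(); lat_list <- list(); labels <- integer(0)
    models <- list()
    off <- 0L
    for (g in groups) {
      cov_g <- draw_covariates(g$n, g$cv, g$label, 0L)
      z <- matrix(stats::rnorm(g$n * 6), g$n, 6)
      z <- sweep(z, 2, g$shift, `+`)
      npts <- 4L * config$R * config$C
      for (i in seq_len(g$n)) {
        m <- template_shape(config, z[i, ], subject_id = cov_g$subject_id[i])
        if (config$noise_sd > 0) {
          eps <- matrix(stats::rnorm(npts * 3L, 0, config$noise_sd), npts, 3L)
          rows <- config$R * config$C
          m$ed_endo$points <- m$ed_endo$points + eps[seq_len(rows), ]
          m$ed_epi$points <- m$ed_epi$points + eps[rows + seq_len(rows), ]
          m$es_endo$points <- m$es_endo$points + eps[2L * rows + seq_len(rows), ]
          m$es_epi$points <- m$es_epi$points + eps[3L * rows + seq_len(rows), ]
        }
        models[[off + i]] <- m
      }
      off <- off + g$n
      cov_list[[length(cov_list) + 1L]] <- cov_g
      lat_list[[length(lat_list) + 1L]] <- z
      labels <- c(labels, rep(g$label, g$n))
    }
    covariates <- do.call(rbind, cov_list)
    # zero-loading latents have no shape derivative; directions undefined
    dirs <- if (all(config$loadings > 0))
      true_component_directions(config) else NULL
    structure(list(models = models, covariates = covariates, labels = labels,
                   true_latents = do.call(rbind, lat_list),
                   true_directions = dirs,
                   config = config),
              class = "lv_cohort")
  })
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("<lv_cohort> %d subjects (%d asymptomatic, %d MI), grid %dx%d\n",
              length(x$models), sum(x$labels == 0), sum(x$labels == 1),
              x$config$R, x$config$C))
  invisible(x)
}

#' Ground-truth generative shape directions
#'
#' Central finite differences of the flattened template shape with respect to
#' each latent at the population mean (latents = 0), normalized to unit
#' length.  These are the oracle directions for parameter-recovery tests.
#'
#' @param config a [generator_config()].
#' @param step finite-difference step in latent units.
#' @return P x 6 matrix of unit columns, named by the index each latent
#'   drives (`edvi, sphericity, rwt, conicity, ef, ls`).
#' @export
true_component_directions <- function(config, step = 1e-3) {
  D <- vapply(1:6, function(l) {
    e <- rep(0, 6); e[l] <- step
    d <- flatten_model(template_shape(config, e)) -
      flatten_model(template_shape(config, -e))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-10)
      stop(sprintf("finite-difference step too small for latent %d (cancellation)", l))
    d / nd
  }, numeric(4L * config$R * config$C * 3L))
  colnames(D) <- c("edvi", "sphericity", "rwt", "conicity", "ef", "ls")
  D
}

#' Calibrate the generator to the reference index targets
#'
#' One-time coordinate search: iteratively simulates a cohort, computes the
#' six indices through the full triangulated-surface pipeline, and applies
#' damped multiplicative updates to the template parameters (matching the
#' asymptomatic group means), the latent loadings (matching the asymptomatic
#' SDs) and the MI latent shifts (matching the MI means).  The shipped
#' [generator_config()] defaults are the output of this routine.
#'
#' @param config starting [generator_config()].
#' @param n cohort size per group used during calibration.
#' @param iters number of coordinate-search sweeps.
#' @param seed RNG seed for the calibration draws.
#' @param verbose print per-iteration diagnostics.
#' @return A calibrated `generator_config`.
#' @export
calibrate_generator <- function(config, n = 1500L, iters = 6L,
                                seed = 42L, verbose = FALSE) {
  tg <- config$targets
  group_means <- function(cfg, which_group, seed_i) {
    cfg2 <- cfg
    if (which_group == "asymp") { cfg2$n_asymp <- n; cfg2$n_mi <- 0L }
    else { cfg2$n_asymp <- 0L; cfg2$n_mi <- n }
    cfg2$seed <- seed_i
    co <- generate_cohort(cfg2)
    idx <- compute_indices_cohort(co$models, co$covariates$height,
                                  co$covariates$weight)
    idx[, c("edvi", "sphericity", "rwt", "conicity", "ef", "ls")]
  }
  eta <- function(p) {  # local elasticity dlog(conicity)/dlog(p)
    (log(profile_conicity(p * 1.05)) - log(profile_conicity(p * 0.95))) /
      (log(1.05) - log(0.95))
  }
  damp <- 0.8
  for (it in seq_len(iters)) {
    ia <- group_means(config, "asymp", seed + it)
    ma <- colMeans(ia); sa <- apply(ia, 2, stats::sd)
    ta <- tg$asymp$mean; tsd <- tg$asymp$sd
    config$L0 <- config$L0 * (ta["edvi"] / ma["edvi"])^(damp / 3)
    config$rho0 <- config$rho0 * (ta["sphericity"] / ma["sphericity"])^(damp / 2)
    config$t0 <- config$t0 * (ta["rwt"] / ma["rwt"])^damp
    config$p0 <- config$p0 *
      exp(damp * log(ta["conicity"] / ma["conicity"]) / eta(config$p0))
    config$lr0 <- config$lr0 * ((1 - ta["ef"]) / (1 - ma["ef"]))^(damp / 2)
    config$lL0 <- 1 - (1 - config$lL0) * (ta["ls"] / ma["ls"])^damp
    for (j in 1:6) {
      nm <- c("edvi", "sphericity", "rwt", "conicity", "ef", "ls")[j]
      config$loadings[j] <- config$loadings[j] * (tsd[nm] / sa[nm])^damp
    }
    im <- group_means(config, "mi", seed + 100L + it)
    mm <- colMeans(im); tm <- tg$mi$mean
    a <- config$loadings; d <- config$mi_shift
    d[1] <- d[1] + damp * log(tm["edvi"] / mm["edvi"]) / (3 * a[1])
    d[2] <- d[2] + damp * log(tm["sphericity"] / mm["sphericity"]) / (6 * a[2])
    d[3] <- d[3] + damp * log(tm["rwt"] / mm["rwt"]) / a[3]
    d[4] <- d[4] + damp * log(tm["conicity"] / mm["conicity"]) /
      (eta(config$p0) * a[4])
    lr_cur <- stats::plogis(stats::qlogis(config$lr0) - a[5] * d[5])
    lr_need <- lr_cur * sqrt(max(1e-6, (1 - tm["ef"]) / (1 - mm["ef"])))
    d[5] <- d[5] - damp * (stats::qlogis(min(0.999, lr_need)) -
                             stats::qlogis(lr_cur)) / a[5]
    lL_cur <- stats::plogis(stats::qlogis(config$lL0) - a[6] * d[6])
    lL_need <- 1 - (1 - lL_cur) * tm["ls"] / mm["ls"]
    d[6] <- d[6] - damp * (stats::qlogis(min(0.999, max(0.5, lL_need))) -
                             stats::qlogis(lL_cur)) / a[6]
    config$mi_shift <- d
    if (verbose) {
      cat(sprintf("iter %d asymp:", it))
      print(round(ma, 4))
      cat(sprintf("iter %d mi:   ", it))
      print(round(mm, 4))
    }
  }
  config
}
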