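# analytic grid builders and cached synthetic cohorts shared across tests

# generic surface of revolution about z: radius_of_u(u) at z = -length * u
revolution_grid <- function(R, C, radius_of_u, length, surface = "endo",
                            frame = "ED", u = seq(0, 1, length.out = R)) {
  th <- 2 * pi * (seq_len(C) - 1) / C
  r <- radius_of_u(u)
  pts <- cbind(rep(r, each = C) * cos(th),
               rep(r, each = C) * sin(th),
               rep(-length * u, each = C))
  surface_grid(pts, R, C, surface, frame)
}

cylinder_grid <- function(R = 6, C = 8, radius = 25, length = 80, ...) {
  revolution_grid(R, C, function(u) rep(radius, length(u)), length, ...)
}

# full sphere/spheroid sampled pole to pole by polar angle (tiny pole offset
# so the cap fans stay non-degenerate)
spheroid_grid <- function(R, C, a, b, ...) {
  phi <- seq(0.001, pi - 0.001, length.out = R)
  th <- 2 * pi * (seq_len(C) - 1) / C
  pts <- do.call(rbind, lapply(phi, function(p)
    cbind(b * sin(p) * cos(th), b * sin(p) * sin(th), a * cos(p))))
  surface_grid(pts, R, C, ...)
}

rot3 <- function(ax, ang) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

transform_grid <- function(grid, Rm = diag(3), shift = c(0, 0, 0)) {
  g <- grid
  g$points <- grid$points %*% t(Rm) +
    matrix(shift, nrow(grid$points), 3, byrow = TRUE)
  g
}

transform_model <- function(model, Rm = diag(3), shift = c(0, 0, 0)) {
  shape_model(transform_grid(model$ed_endo, Rm, shift),
              transform_grid(model$ed_epi, Rm, shift),
              transform_grid(model$es_endo, Rm, shift),
              transform_grid(model$es_epi, Rm, shift),
              subject_id = model$subject_id)
}

# concentric-cylinder shape model (analytic RWT/EF fixtures)
tube_model <- function(R = 6, C = 8, r_endo = 25, wall = 10, length = 80,
                       es_scale = 1) {
  ed_endo <- cylinder_grid(R, C, r_endo, length, surface = "endo", frame = "ED")
  ed_epi <- cylinder_grid(R, C, r_endo + wall, length, surface = "epi", frame = "ED")
  mk <- function(g, surface, frame) surface_grid(g$points * es_scale,
                                                 R, C, surface, frame)
  shape_model(ed_endo, ed_epi, mk(ed_endo, "endo", "ES"),
              mk(ed_epi, "epi", "ES"))
}

# cached cohorts: built once per test run, reused across files
.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function(n_asymp, n_mi, seed, noise_sd = 0.5) {
  key <- sprintf("co_%d_%d_%d_%s", n_asymp, n_mi, seed, noise_sd)
  if (is.null(.fixtures[[key]])) {
    cfg <- generator_config(n_asymp = n_asymp, n_mi = n_mi, seed = seed,
                            noise_sd = noise_sd)
    co <- generate_cohort(cfg)
    idx <- compute_indices_cohort(co$models, co$covariates$height,
                                  co$covariates$weight)
    X <- do.call(rbind, lapply(co$models, flatten_model))
    .fixtures[[key]] <- list(cohort = co, indices = idx, X = X)
  }
  .fixtures[[key]]
}

index_cols <- c("edvi", "sphericity", "ef", "rwt", "conicity", "ls")

# Gram-Schmidt orthonormalization of truth directions in extraction order
orthogonalize_truths <- function(td) {
  for (i in seq_len(ncol(td))) {
    if (i > 1) {
      prev <- td[, 1:(i - 1), drop = FALSE]
      td[, i] <- td[, i] - prev %*% crossprod(prev, td[, i])
    }
    td[, i] <- td[, i] / sqrt(sum(td[, i]^2))
  }
  td
}
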