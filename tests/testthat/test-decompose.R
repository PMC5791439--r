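test_that("deflation is an idempotent orthogonal projector", {
  set.seed(20)
  X <- matrix(rnorm(15 * 8), 15, 8)
  b <- rnorm(8); b <- b / sqrt(sum(b^2))
  d1 <- deflate(X, b)
  expect_lt(max(abs(d1$X %*% b)), 1e-10)
  d2 <- deflate(d1, b)
  expect_equal(d2$X, d1$X, tolerance = 1e-12)
  # Frobenius Pythagoras: ||X||^2 - ||X'||^2 = ||Xb||^2
  sm <- center_shapes(X)
  expect_equal(sum(sm$X^2) - sum(d1$X^2), sum((sm$X %*% b)^2),
               tolerance = 1e-9)
  expect_error(deflate(X, b * 2), "unit")
})

test_that("deflation drops the rank by one for in-rowspace directions", {
  set.seed(21)
  X <- center_shapes(matrix(rnorm(20 * 6), 20, 6))
  b <- crossprod(X$X, rnorm(20))[, 1]
  b <- b / sqrt(sum(b^2))
  rank_of <- function(M) sum(svd(M)$d > 1e-8 * max(svd(M)$d))
  expect_equal(rank_of(deflate(X, b)$X), rank_of(X$X) - 1)
})

test_that("components are orthonormal and residuals orthogonal to them", {
  fx <- fixture_cohort(60, 20, seed = 305)
  for (m in c(1L, 10L)) {
    dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = m)
    G <- crossprod(dec$components)
    expect_lt(max(abs(G - diag(6))), 1e-8)
    expect_lt(max(abs(dec$residual_X %*% dec$components)), 1e-6)
  }
})

test_that("one-factor decomposition decorrelates later scores from earlier indices", {
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1)
  for (i in 1:5) for (j in (i + 1):6) {
    r <- cor(fx$indices[[dec$order[i]]], dec$scores[, j])
    expect_lt(abs(r), 1e-8)
  }
})

test_that("deflation conserves Frobenius norm across the extraction", {
  fx <- fixture_cohort(60, 20, seed = 305)
  sm <- center_shapes(fx$X)
  dec <- remodel_decompose(sm, fx$indices[index_cols], M = 1)
  removed <- sum(dec$scores^2)
  expect_equal(sum(sm$X^2), sum(dec$residual_X^2) + removed,
               tolerance = 1e-9)
})

test_that("M=1 extraction equals the brute-force X'y projection cascade", {
  # independent oracle: no SIMPLS machinery, just normalized cross-covariance
  # projections with explicit deflation
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1)
  Xc <- scale(fx$X, scale = FALSE)
  for (nm in dec$order) {
    y <- fx$indices[[nm]]
    b <- crossprod(Xc, y - mean(y))[, 1]
    b <- b / sqrt(sum(b^2))
    s <- Xc %*% b
    expect_lt(max(abs(s - dec$scores[, nm])), 1e-8 * sd(s))
    expect_gte(sum(b * dec$components[, nm]), 1 - 1e-10)
    Xc <- Xc - s %*% t(b)
  }
})

test_that("a single latent direction driving the response is recovered", {
  # cohort with one latent direction d and isotropic noise, SNR >= 10
  set.seed(22)
  P <- 300; N <- 150
  d <- rnorm(P); d <- d / sqrt(sum(d^2))
  z <- rnorm(N, sd = 10)
  X <- z %*% t(d) + matrix(rnorm(N * P, sd = sqrt(100 / (10 * P))), N, P)
  y <- z + rnorm(N, sd = 0.1)
  dec <- remodel_decompose(X, data.frame(edvi = y), M = 1, order = "edvi")
  expect_lt(component_angle(dec$components[, 1], d), 5)
})

test_that("scoring new data reproduces training scores and is linear", {
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1)
  expect_equal(predict(dec, fx$X), dec$scores, tolerance = 1e-10)
  expect_equal(remodeling_scores(fx$X, dec), dec$scores, tolerance = 1e-10)
  # the training mean shape maps to all-zero scores
  expect_equal(as.numeric(predict(dec, rbind(dec$mean_shape))), rep(0, 6),
               tolerance = 1e-8)
})

test_that("estimate_index rescales scores back to index units", {
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1)
  expect_equal(estimate_index(0, dec, "edvi"), unname(dec$y_mean["edvi"]))
  expect_equal(estimate_index(2, dec, "ef"),
               2 * unname(dec$beta_prime_norm["ef"]) + unname(dec$y_mean["ef"]))
  # equals the step fit's prediction for a training subject (first index:
  # the step operates on the original centered matrix)
  f1 <- simpls_fit(center_shapes(fx$X), fx$indices$edvi, M = 1)
  expect_equal(unname(estimate_index(dec$scores[5, "edvi"], dec, "edvi")),
               unname(predict(f1, fx$X[5, , drop = FALSE])), tolerance = 1e-8)
})

test_that("component_angle covers identity, orthogonality and sign", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(component_angle(e1, e1), 0)
  expect_equal(component_angle(e1, e2), 90)
  expect_equal(component_angle(e1, -e1), 180)
  expect_error(component_angle(e1 * 2, e2), "unit")
})

test_that("rms_angle aggregates trial angles correctly", {
  ref <- diag(3)[, 1:2]
  same <- list(ref, ref, ref)
  expect_equal(unname(rms_angle(same, ref)), c(0, 0))
  rot <- cbind(c(cos(pi / 6), sin(pi / 6), 0), c(0, 0, 1))
  expect_equal(unname(rms_angle(list(rot), ref)),
               c(30, component_angle(ref[, 2], rot[, 2])))
  expect_error(rms_angle(list(ref[, 1, drop = FALSE]), ref), "mismatch")
})

test_that("morphing moves the computed index in the component's direction", {
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1)
  expect_equal(morph_shape(dec, "edvi", 0), dec$mean_shape)
  a <- 1.5
  expect_equal(morph_shape(dec, "edvi", a) + morph_shape(dec, "edvi", -a),
               2 * dec$mean_shape)
  co <- fx$cohort
  sd_sc <- sd(dec$scores[, "edvi"])
  mean_model <- unflatten_model(dec$mean_shape, co$config$R, co$config$C)
  up_model <- unflatten_model(morph_shape(dec, "edvi", 2 * sd_sc),
                              co$config$R, co$config$C)
  edv0 <- surface_volume(close_surface(mean_model$ed_endo))
  edv2 <- surface_volume(close_surface(up_model$ed_endo))
  expect_gt(edv2, edv0)
})

test_that("explicit order is honored and unknown names rejected", {
  fx <- fixture_cohort(60, 20, seed = 305)
  ord <- c("ef", "edvi", "ls")
  dec <- remodel_decompose(fx$X, fx$indices[ord], M = 1, order = ord)
  expect_identical(dec$order, ord)
  expect_error(
    remodel_decompose(fx$X, fx$indices[index_cols], M = 1,
                      order = c("edvi", "bogus")), "bogus")
})

test_that("auto ordering picks the largest one-step score variance first", {
  fx <- fixture_cohort(60, 20, seed = 305)
  dec <- remodel_decompose(fx$X, fx$indices[index_cols], M = 1, order = "auto")
  # recompute each index's one-step score variance on the original matrix
  sm <- center_shapes(fx$X)
  v1 <- vapply(index_cols, function(nm) {
    f <- simpls_fit(sm, fx$indices[[nm]], M = 1)
    b <- f$beta_prime / sqrt(sum(f$beta_prime^2))
    s <- sm$X %*% b
    mean(s^2) - mean(s)^2
  }, numeric(1))
  expect_identical(dec$order[1], names(which.max(v1)))
  expect_true(all(sort(dec$order) == sort(index_cols)))
})
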