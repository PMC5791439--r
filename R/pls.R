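#' Column-center a raw shape matrix
#'
#' Builds the cohort shape matrix used by PLS and PCA: rows are flattened
#' shape vectors, columns are centered to zero mean and the column means are
#' retained so new subjects (and morphed shapes) can be mapped in and out of
#' the centered space.
#'
#' @param raw_X numeric N x P matrix (N subjects, P shape features).
#' @param subject_ids optional length-N identifiers.
#' @return Object of class `shape_matrix`: list with `X` (centered matrix),
#'   `column_means` and `subject_ids`.
#' @export
center_shapes <- function(raw_X, subject_ids = rownames(raw_X)) {
  raw_X <- as.matrix(raw_X)
  if (!all(is.finite(raw_X))) stop("shape matrix contains non-finite entries")
  if (nrow(raw_X) < 2L) stop("need at least 2 subjects")
  mu <- colMeans(raw_X)
  structure(list(X = sweep(raw_X, 2, mu), column_means = mu,
                 subject_ids = subject_ids),
            class = "shape_matrix")
}

#' @export
print.shape_matrix <- function(x, ...) {
  cat(sprintf("<shape_matrix> %d subjects x %d features (centered)\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

as_shape_matrix <- function(X) {
  if (inherits(X, "shape_matrix")) X else center_shapes(X)
}

# apply stored training centering to new raw rows
center_with <- function(X_new, column_means) {
  X_new <- if (is.matrix(X_new)) X_new else matrix(X_new, nrow = 1)
  if (ncol(X_new) != length(column_means))
    stop("dimension mismatch with training shape matrix")
  sweep(X_new, 2, column_means)
}

#' SIMPLS partial least squares regression (single response)
#'
#' Fits `y = X beta' + e` with `M` latent factors by the SIMPLS algorithm
#' (de Jong 1993): factors maximize the covariance between response and
#' predictors, with the cross-covariance vector deflated through an
#' orthonormal loading basis at each step.  `X` is column-centered and `y` is
#' centered internally; no intercept beyond the response mean.
#'
#' For `M = 1` the coefficient vector is exactly proportional to `t(X) %*% y`.
#' For `M = min(N - 1, P)` on full-rank data it reproduces the ordinary
#' least-squares solution.
#'
#' @param X a `shape_matrix` (or raw matrix, centered on the fly).
#' @param y numeric response vector, length N.
#' @param M number of latent factors, `1 <= M <= min(N - 1, P)`.
#' @return Object of class `simpls`: `beta_prime` (length-P coefficients),
#'   `y_mean`, `M`, `weights` (P x M projection weights R), `loadings`
#'   (P x M), `scores` (N x M factor scores T), `q` (response loadings),
#'   `residuals`, `column_means`, and `beta_by_factor` (P x M matrix of
#'   coefficient vectors for 1..M factors).
#' @references de Jong, S. (1993). SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems, 18, 251-263.
#' @export
simpls_fit <- function(X, y, M = 1L) {
  sm <- as_shape_matrix(X)
  Xc <- sm$X
  N <- nrow(Xc); P <- ncol(Xc)
  if (length(y) != N) stop("length(y) must match nrow(X)")
  if (!all(is.finite(y))) stop("y contains non-finite values")
  M <- as.integer(M)
  if (M < 1L || M > min(N - 1L, P))
    stop(sprintf("M must be in 1..min(N-1, P) = %d", min(N - 1L, P)))
  y_mean <- mean(y)
  yc <- y - y_mean
  if (sqrt(sum(yc^2)) < 1e-12 * max(1, abs(y_mean)))
    stop("response has zero variance")

  s <- crossprod(Xc, yc)               # P x 1 cross-covariance
  Rw <- matrix(0, P, M); Pl <- matrix(0, P, M)
  Tt <- matrix(0, N, M); qv <- numeric(M)
  Vb <- matrix(0, P, M)                # orthonormal basis of loadings
  for (m in seq_len(M)) {
    r <- s                             # univariate y: weight = deflated S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) stop(sprintf("factor %d collapsed (rank exhausted)", m))
    t <- t / nt; r <- r / nt
    p <- crossprod(Xc, t)
    q <- sum(yc * t)
    v <- p
    if (m > 1L) {
      vprev <- Vb[, 1:(m - 1L), drop = FALSE]
      v <- v - vprev %*% crossprod(vprev, p)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    Rw[, m] <- r; Pl[, m] <- p; Tt[, m] <- t; qv[m] <- q; Vb[, m] <- v
  }
  # column m of beta_by_factor = sum_{i<=m} q_i * r_i
  beta_by_factor <- apply(sweep(Rw, 2, qv, `*`), 1, cumsum)
  beta_by_factor <- if (M == 1L) matrix(beta_by_factor, ncol = 1L) else t(beta_by_factor)
  beta_prime <- beta_by_factor[, M]
  fit <- structure(list(beta_prime = beta_prime, y_mean = y_mean, M = M,
                        weights = Rw, loadings = Pl, scores = Tt, q = qv,
                        beta_by_factor = beta_by_factor,
                        residuals = as.numeric(yc - Xc %*% beta_prime),
                        column_means = sm$column_means),
                   class = "simpls")
  fit
}

#' @export
print.simpls <- function(x, ...) {
  cat(sprintf("<simpls> %d latent factor(s), P = %d, ||beta'|| = %.4g\n",
              x$M, length(x$beta_prime), sqrt(sum(x$beta_prime^2))))
  invisible(x)
}

#' @export
coef.simpls <- function(object, ...) object$beta_prime

#' Predict from a SIMPLS fit
#'
#' `y_hat = X_new %*% beta' + y_mean`, with `X_new` centered by the training
#' column means.
#'
#' @param object a [simpls_fit()] result.
#' @param newdata raw (uncentered) matrix or vector of shape features; when
#'   omitted, training fitted values are returned via residuals.
#' @param centered set `TRUE` if `newdata` is already centered with the
#'   training means.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.simpls <- function(object, newdata, centered = FALSE, ...) {
  Xn <- if (centered) {
    Xn <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
    if (ncol(Xn) != length(object$beta_prime)) stop("dimension mismatch")
    Xn
  } else center_with(newdata, object$column_means)
  as.numeric(Xn %*% object$beta_prime + object$y_mean)
}

#' @export
residuals.simpls <- function(object, ...) object$residuals

#' Cross-validated choice of the number of latent factors
#'
#' K-fold cross-validation of SIMPLS prediction error for `M = 1..M_max`.
#' Folds are assigned by a seeded permutation, stratified by `labels` when
#' provided (each fold receives a proportional share of each group).
#'
#' @param X `shape_matrix` or raw matrix.
#' @param y response vector.
#' @param folds number of folds (>= 2); `folds = N` gives leave-one-out.
#' @param M_max largest number of latent factors to assess.
#' @param labels optional group labels for stratified fold assignment.
#' @param seed integer seed controlling the fold permutation.
#' @return Numeric vector `mse[1..M_max]` of held-out mean squared errors.
#' @export
cross_validate_M <- function(X, y, folds = 10L, M_max, labels = NULL,
                             seed = 1L) {
  sm <- as_shape_matrix(X)
  N <- nrow(sm$X)
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds")
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    if (is.null(labels)) {
      sample(rep_len(seq_len(folds), N))
    } else {
      f <- integer(N)
      for (g in unique(labels)) {
        idx <- which(labels == g)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    }
  })
  if (min(table(rng)) < 1L || N - max(table(rng)) < 2L)
    stop("a fold has fewer than 2 training samples")
  err <- matrix(NA_real_, N, M_max)
  for (k in seq_len(folds)) {
    test <- which(rng == k)
    if (length(test) == 0L) next
    train <- setdiff(seq_len(N), test)
    if (length(train) < 2L) stop("a fold leaves fewer than 2 training samples")
    raw_train <- sweep(sm$X[train, , drop = FALSE], 2, -sm$column_means)
    sm_tr <- center_shapes(raw_train)
    m_fit <- min(M_max, length(train) - 1L, ncol(sm$X))
    fit <- simpls_fit(sm_tr, y[train], M = m_fit)
    Xte <- center_with(
      sweep(sm$X[test, , drop = FALSE], 2, -sm$column_means),
      sm_tr$column_means)
    for (m in seq_len(M_max)) {
      b <- fit$beta_by_factor[, min(m, m_fit)]
      pred <- as.numeric(Xte %*% b + fit$y_mean)
      err[test, m] <- (y[test] - pred)^2
    }
  }
  colMeans(err, na.rm = TRUE)
}
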