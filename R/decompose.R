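#' Deflate a shape matrix along a unit component
#'
#' Removes the projection of every row onto a unit vector:
#' `X' = X - X beta t(beta)`, so `X' beta = 0`.  Applying the same deflation
#' twice is a no-op (orthogonal projector).
#'
#' @param X a `shape_matrix` (or raw matrix, centered first).
#' @param beta unit length-P vector.
#' @return A `shape_matrix` with the deflated `X` and unchanged metadata.
#' @export
deflate <- function(X, beta) {
  sm <- as_shape_matrix(X)
  nb <- sqrt(sum(beta^2))
  if (abs(nb - 1) > 1e-8) stop("beta must be a unit vector")
  if (length(beta) != ncol(sm$X)) stop("dimension mismatch")
  sm$X <- sm$X - (sm$X %*% beta) %*% t(beta)
  sm
}

index_order_default <- c("edvi", "sphericity", "ef", "rwt", "conicity", "ls")

#' Orthogonal remodeling decomposition of a shape cohort
#'
#' The central fit of the package.  Each clinical remodeling index is
#' regressed on the (residual) shape matrix by SIMPLS PLS ([simpls_fit()]);
#' the unit-normalized coefficient vector is the *remodeling component* for
#' that index; remodeling scores are the projections of the residual shapes
#' onto it; and the shape space is deflated ([deflate()]) before the next
#' index is processed.  Because each deflation leaves the residual matrix
#' orthogonal to the extracted component, the K components form an
#' orthonormal basis, and with a single latent factor (`M = 1`) the scores of
#' every later component have exactly zero correlation with every earlier
#' index.
#'
#' @param X raw N x P matrix of flattened shape vectors, or a `shape_matrix`.
#' @param indices data.frame or matrix of remodeling indices (one column per
#'   index, finite, nonzero variance).  Columns are matched by name to
#'   `order`.
#' @param M number of PLS latent factors per index (1 reproduces the
#'   zero-correlation decoupling; larger M tracks each index more closely).
#' @param order either `"fixed"` (the default extraction order `edvi,
#'   sphericity, ef, rwt, conicity, ls`, i.e. decreasing remodeling-score
#'   variance in the reference cohort), `"auto"` (greedy: at each step pick
#'   the remaining index whose one-step remodeling-score variance on the
#'   current residual is largest; ties broken alphabetically), or an explicit
#'   character vector of index column names.
#' @return Object of class `remodel_decomp` with elements
#'   `components` (P x K matrix of orthonormal unit vectors, one column per
#'   index), `order` (index names in extraction order), `scores` (N x K
#'   remodeling scores, Eq. `Y_score = X beta` at each step),
#'   `beta_prime_norm`, `y_mean` and `score_variance` (per component, the
#'   population 1/N variance), `M`, `column_means`, `mean_shape` (the
#'   training column means), `residual_X` (final deflated matrix) and
#'   `subject_ids`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 12), 40, 12)
#' idx <- data.frame(a = X[, 1] + rnorm(40, sd = .1),
#'                   b = X[, 5] + rnorm(40, sd = .1))
#' fit <- remodel_decompose(X, idx, M = 1, order = c("a", "b"))
#' crossprod(fit$components)  # ~ identity
#' @export
remodel_decompose <- function(X, indices, M = 1L, order = "fixed") {
  sm <- as_shape_matrix(X)
  indices <- as.data.frame(indices)
  if (!all(vapply(indices, function(v) all(is.finite(v)), logical(1))))
    stop("index columns must be finite")
  sds <- vapply(indices, stats::sd, numeric(1))
  if (any(sds < 1e-12))
    stop("zero-variance index column(s): ",
         paste(names(indices)[sds < 1e-12], collapse = ", "))
  if (nrow(indices) != nrow(sm$X))
    stop("indices and shape matrix disagree on N")

  auto <- FALSE
  if (identical(order, "auto")) {
    auto <- TRUE
    remaining <- sort(names(indices))
  } else {
    if (identical(order, "fixed"))
      order <- intersect(index_order_default, names(indices))
    if (!length(order) || !all(order %in% names(indices)))
      stop("unknown index name(s) in 'order': ",
           paste(setdiff(order, names(indices)), collapse = ", "))
    remaining <- order
  }

  N <- nrow(sm$X); P <- ncol(sm$X)
  K <- length(remaining)
  comp <- matrix(0, P, K)
  scores <- matrix(0, N, K)
  bnorm <- ymean <- svar <- numeric(K)
  picked <- character(K)
  Xcur <- sm
  for (step in seq_len(K)) {
    if (auto) {
      # greedy: largest one-step remodeling-score variance on the residual
      vars <- vapply(remaining, function(nm) {
        f <- simpls_fit(Xcur, indices[[nm]], M = M)
        nb <- sqrt(sum(f$beta_prime^2))
        if (nb < 1e-12) return(0)
        s <- as.numeric(Xcur$X %*% (f$beta_prime / nb))
        mean(s^2) - mean(s)^2
      }, numeric(1))
      nm <- remaining[which.max(vars)]  # which.max: first of ties (sorted)
    } else {
      nm <- remaining[1L]
    }
    remaining <- setdiff(remaining, nm)
    fit <- simpls_fit(Xcur, indices[[nm]], M = M)
    nb <- sqrt(sum(fit$beta_prime^2))
    if (nb < 1e-10 * sqrt(P))
      stop(sprintf(
        "index '%s' (step %d) is unexplainable from the residual shape space (||beta'|| ~ 0)",
        nm, step))
    beta <- fit$beta_prime / nb
    s <- as.numeric(Xcur$X %*% beta)
    comp[, step] <- beta
    scores[, step] <- s
    bnorm[step] <- nb
    ymean[step] <- fit$y_mean
    svar[step] <- mean(s^2) - mean(s)^2  # population (1/N) variance
    picked[step] <- nm
    Xcur <- deflate(Xcur, beta)
  }
  colnames(comp) <- picked
  colnames(scores) <- picked
  names(bnorm) <- names(ymean) <- names(svar) <- picked
  structure(list(components = comp, order = picked, scores = scores,
                 beta_prime_norm = bnorm, y_mean = ymean,
                 score_variance = svar, M = M,
                 column_means = sm$column_means,
                 mean_shape = sm$column_means,
                 residual_X = Xcur$X,
                 subject_ids = sm$subject_ids),
            class = "remodel_decomp")
}

#' @export
print.remodel_decomp <- function(x, ...) {
  cat(sprintf("Orthogonal remodeling decomposition (M = %d, K = %d, N = %d, P = %d)\n",
              x$M, length(x$order), nrow(x$scores), nrow(x$components)))
  cat("extraction order:", paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.remodel_decomp <- function(object, ...) {
  tab <- data.frame(step = seq_along(object$order),
                    index = object$order,
                    beta_prime_norm = object$beta_prime_norm,
                    index_mean = object$y_mean,
                    score_variance = object$score_variance,
                    row.names = NULL)
  structure(list(M = object$M, table = tab,
                 gram_dev = max(abs(crossprod(object$components) -
                                      diag(length(object$order))))),
            class = "summary.remodel_decomp")
}

#' @export
print.summary.remodel_decomp <- function(x, ...) {
  cat(sprintf("Orthogonal remodeling decomposition (M = %d)\n", x$M))
  print(x$table, digits = 4)
  cat(sprintf("max |B'B - I| = %.2e\n", x$gram_dev))
  invisible(x)
}

#' @export
coef.remodel_decomp <- function(object, ...) object$components

#' @export
residuals.remodel_decomp <- function(object, ...) object$residual_X

#' Remodeling scores for (new) shape data
#'
#' Projects each subject onto the remodeling components by sequential
#' projection with the stored unit vectors (project onto component 1,
#' subtract, project onto component 2, ...), which for an orthonormal basis
#' equals direct projection.  On the training data this reproduces the stored
#' scores exactly.
#'
#' @param object a [remodel_decompose()] fit.
#' @param newdata raw N x P matrix of flattened shape vectors (uncentered) or
#'   a single vector; when missing, the stored training scores are returned.
#' @param centered set `TRUE` if `newdata` is already centered with the
#'   training column means.
#' @param ... unused.
#' @return N x K matrix of remodeling scores.
#' @export
predict.remodel_decomp <- function(object, newdata, centered = FALSE, ...) {
  if (missing(newdata)) return(object$scores)
  Xn <- if (centered) {
    if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
    newdata
  } else center_with(newdata, object$column_means)
  if (ncol(Xn) != nrow(object$components)) stop("dimension mismatch")
  K <- ncol(object$components)
  out <- matrix(0, nrow(Xn), K, dimnames = list(NULL, object$order))
  for (i in seq_len(K)) {
    b <- object$components[, i]
    s <- as.numeric(Xn %*% b)
    out[, i] <- s
    Xn <- Xn - s %*% t(b)
  }
  out
}

#' Remodeling scores (explicit-name wrapper)
#'
#' @param X raw shape matrix or vector (uncentered).
#' @param decomp a [remodel_decompose()] fit.
#' @return N x K score matrix; see [predict.remodel_decomp()].
#' @export
remodeling_scores <- function(X, decomp) predict(decomp, X)

#' Estimate a clinical index from a remodeling score
#'
#' Rescales a remodeling score back to index units:
#' `score * ||beta'|| + mean(index)`.
#'
#' @param score numeric score value(s).
#' @param decomp a [remodel_decompose()] fit.
#' @param index index name (one of `decomp$order`).
#' @return Estimated index value(s).
#' @export
estimate_index <- function(score, decomp, index) {
  if (!index %in% decomp$order) stop("unknown index: ", index)
  score * decomp$beta_prime_norm[[index]] + decomp$y_mean[[index]]
}

#' Angle between two shape components
#'
#' `acos(b1 . b2)` in degrees.  The sign of a PLS component is pinned by its
#' index (unlike PCA), so anti-parallel components are reported as 180 deg.
#'
#' @param b1,b2 unit vectors of equal length.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
component_angle <- function(b1, b2) {
  if (abs(sqrt(sum(b1^2)) - 1) > 1e-6 || abs(sqrt(sum(b2^2)) - 1) > 1e-6)
    stop("component_angle expects unit vectors")
  acos(max(-1, min(1, sum(b1 * b2)))) * 180 / pi
}

#' RMS angle between repeated component sets and a reference
#'
#' For each component, the root-mean-square over trials of the angle to the
#' matched reference component — the stability summary used in subsampling
#' experiments.
#'
#' @param component_sets list of P x K matrices (one per trial), columns
#'   matched to the reference order.
#' @param reference P x K matrix of reference components.
#' @return Length-K vector of RMS angles (degrees), named by the reference
#'   column names.
#' @export
rms_angle <- function(component_sets, reference) {
  K <- ncol(reference)
  ang2 <- sapply(component_sets, function(B) {
    if (ncol(B) != K) stop("mismatched number of components")
    vapply(seq_len(K), function(i)
      component_angle(B[, i], reference[, i])^2, numeric(1))
  })
  if (is.null(dim(ang2))) ang2 <- matrix(ang2, nrow = K)
  out <- sqrt(rowMeans(ang2))
  names(out) <- colnames(reference)
  out
}

#' Morph the mean shape along a remodeling component
#'
#' `mean_shape + amount * beta`, in raw (uncentered) shape coordinates, ready
#' for [unflatten_model()] and mesh export.
#'
#' @param decomp a [remodel_decompose()] fit.
#' @param index index name of the component to morph along.
#' @param amount displacement in score units (e.g. multiples of the score SD).
#' @param mean_shape base shape vector; defaults to the training mean.
#' @return Length-P shape vector.
#' @export
morph_shape <- function(decomp, index, amount, mean_shape = decomp$mean_shape) {
  if (!index %in% decomp$order) stop("unknown index: ", index)
  if (!is.finite(amount)) stop("amount must be finite")
  mean_shape + amount * decomp$components[, index]
}

#' Score-variance bar plot of a decomposition
#'
#' @param x a [remodel_decompose()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.remodel_decomp <- function(x, ...) {
  graphics::barplot(x$score_variance, names.arg = x$order,
                    ylab = "remodeling score variance (mm^2)",
                    xlab = "component (extraction order)",
                    main = sprintf("Shape variance explained (M = %d)", x$M),
                    ...)
  invisible(x)
}
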