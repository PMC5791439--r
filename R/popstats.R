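#' Principal component analysis of a shape matrix
#'
#' Top-k eigenvectors of the sample covariance of the centered shape matrix,
#' computed through the N x N Gram matrix when P > N (the usual shape-model
#' regime).  Components are unit norm in variance-descending order, with the
#' sign convention that the largest-magnitude loading is positive.
#'
#' @param X `shape_matrix` or raw matrix.
#' @param k number of components, `k <= min(N - 1, P)`.
#' @return List with `components` (P x k), `scores` (N x k, `X %*%
#'   components`), and `explained_variance` (eigenvalues of the sample
#'   covariance, denominator N - 1).
#' @export
pca_components <- function(X, k) {
  sm <- as_shape_matrix(X)
  Xc <- sm$X
  N <- nrow(Xc); P <- ncol(Xc)
  k <- as.integer(k)
  if (k < 1L || k > min(N - 1L, P))
    stop(sprintf("k must be in 1..min(N-1, P) = %d", min(N - 1L, P)))
  if (P > N) {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    V <- crossprod(Xc, U)
    V <- sweep(V, 2, sqrt(d2), `/`)
  } else {
    sv <- svd(Xc, nu = 0, nv = k)
    V <- sv$v
    d2 <- sv$d[seq_len(k)]^2
  }
  # sign convention: largest-|loading| entry positive
  for (i in seq_len(k)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) V[, i] <- -V[, i]
  }
  list(components = V, scores = Xc %*% V,
       explained_variance = d2 / (N - 1))
}

#' Logistic-regression characterization of disease
#'
#' Maximum-likelihood logistic regression (binomial IRLS via [stats::glm()])
#' of a 0/1 disease label on shape features (component scores, PCA scores or
#' clinical indices) plus baseline covariates, with the report columns used
#' in clinical model tables: Wald standard errors and p-values, standardized
#' coefficients (coefficient times the sample SD of the predictor), odds
#' ratios and Wald 95% confidence intervals.
#'
#' @param features N x q data.frame/matrix of predictors of interest.
#' @param covariates optional N x c data.frame/matrix of baseline covariates
#'   (age, sex, BMI, DBP, smoking, diabetes ... entered untransformed;
#'   binary covariates coded 0/1).
#' @param labels 0/1 vector (1 = disease present).
#' @return Object of class `lv_logistic`: the report `table`, `deviance`,
#'   `aic` (= deviance + 2k), `bic` (= deviance + k log n), `n`, `k`,
#'   `fitted` probabilities, `labels` and the underlying `glm` object.
#' @export
fit_logistic <- function(features, covariates = NULL, labels) {
  features <- as.data.frame(features)
  df <- if (is.null(covariates)) features else
    cbind(features, as.data.frame(covariates))
  if (anyDuplicated(names(df))) stop("duplicated predictor names")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (nrow(df) != length(labels)) stop("predictors and labels disagree on N")
  dat <- cbind(.y = labels, df)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)))
  if (!fit$converged)
    stop("IRLS did not converge (possible separation)")
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  preds <- rownames(sm)[-1]
  sdv <- vapply(preds, function(nm)
    stats::sd(stats::model.matrix(fit)[, nm]), numeric(1))
  # separation: scale-free coefficient norm diverges / fit is exact
  if (max(abs(cf[-1]) * sdv) > 50 ||
      all(abs(fit$fitted.values - labels) < 1e-8))
    stop("perfect separation: coefficients diverge")
  tab <- data.frame(
    variable = preds,
    coefficient = sm[-1, 1],
    std_error = sm[-1, 2],
    p_value = sm[-1, 4],
    standardized_coefficient = sm[-1, 1] * sdv,
    odds_ratio = exp(sm[-1, 1]),
    or_ci_low = exp(sm[-1, 1] - stats::qnorm(0.975) * sm[-1, 2]),
    or_ci_high = exp(sm[-1, 1] + stats::qnorm(0.975) * sm[-1, 2]),
    row.names = NULL)
  n <- length(labels)
  kpar <- length(cf)
  dev <- as.numeric(stats::deviance(fit))
  structure(list(table = tab, intercept = unname(cf[1]),
                 deviance = dev, aic = dev + 2 * kpar,
                 bic = dev + kpar * log(n), n = n, k = kpar,
                 fitted = as.numeric(fit$fitted.values),
                 labels = labels, glm = fit,
                 feature_names = names(features)),
            class = "lv_logistic")
}

#' @export
print.lv_logistic <- function(x, ...) {
  cat(sprintf("Logistic regression: n = %d, k = %d, deviance = %.1f, AIC = %.1f, BIC = %.1f\n",
              x$n, x$k, x$deviance, x$aic, x$bic))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.lv_logistic <- function(object, ...) {
  stats::setNames(object$table$coefficient, object$table$variable)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the proportion of (positive, negative) pairs in
#' which the positive subject scores higher, ties counting one half.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 vector, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-sided paired DeLong test for AUC difference
#'
#' Tests whether the AUC of model A exceeds that of model B on the same
#' subjects, using the DeLong covariance estimate of the paired AUC
#' difference (via [pROC::roc.test()]).
#'
#' @param predsA,predsB predicted probabilities/scores from the two models,
#'   same subjects in the same order.
#' @param labels 0/1 vector.
#' @param alternative `"greater"` (AUC_A > AUC_B, default) or `"less"`.
#' @return List with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_paired_test <- function(predsA, predsB, labels,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(predsA) != length(predsB) || length(predsA) != length(labels))
    stop("predictions and labels must cover the same subjects")
  a <- auc(predsA, labels); b <- auc(predsB, labels)
  if (isTRUE(all.equal(predsA, predsB, tolerance = 1e-12))) {
    warning("identical predictions: AUC difference degenerate, p = 0.5")
    return(list(auc_a = a, auc_b = b, p_value = 0.5))
  }
  p <- tryCatch({
    ra <- pROC::roc(labels, predsA, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, predsB, quiet = TRUE, direction = "<")
    as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = TRUE,
                              alternative = alternative)$p.value)
  }, error = function(e) {
    warning("degenerate AUC variance: ", conditionMessage(e), "; p = 0.5")
    0.5
  })
  list(auc_a = a, auc_b = b, p_value = p)
}

#' Pearson correlation table between two sets of variables
#'
#' @param left N x a data.frame/matrix.
#' @param right N x b data.frame/matrix.
#' @return a x b matrix of Pearson correlations; zero-variance columns yield
#'   `NA` entries with a warning.
#' @export
correlation_table <- function(left, right) {
  L <- as.matrix(as.data.frame(left)); Rm <- as.matrix(as.data.frame(right))
  sdl <- apply(L, 2, stats::sd); sdr <- apply(Rm, 2, stats::sd)
  if (any(sdl < 1e-14) || any(sdr < 1e-14))
    warning("zero-variance column(s): correlations undefined (NA)")
  suppressWarnings(stats::cor(L, Rm))
}

#' Compare fitted logistic models
#'
#' Tabulates deviance, AIC, BIC and AUC for a set of models fitted on the
#' same subjects, plus one-sided pairwise DeLong tests (row model AUC greater
#' than column model AUC).
#'
#' @param models named list of [fit_logistic()] objects.
#' @param labels 0/1 vector shared by all models.
#' @return Object of class `lv_model_comparison`: `table` (per-model fit
#'   measures with the best model flagged per criterion) and `p_auc`
#'   (pairwise one-sided p-values).
#' @export
compare_models <- function(models, labels) {
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  labels <- as.numeric(labels)
  for (m in models)
    if (m$n != length(labels)) stop("models fitted on different subjects")
  tab <- data.frame(
    model = names(models),
    deviance = vapply(models, `[[`, numeric(1), "deviance"),
    aic = vapply(models, `[[`, numeric(1), "aic"),
    bic = vapply(models, `[[`, numeric(1), "bic"),
    auc = vapply(models, function(m) auc(m$fitted, labels), numeric(1)),
    row.names = NULL)
  nm <- length(models)
  p <- matrix(NA_real_, nm, nm, dimnames = list(names(models), names(models)))
  for (i in seq_len(nm)) for (j in seq_len(nm)) if (i != j)
    p[i, j] <- suppressWarnings(
      delong_paired_test(models[[i]]$fitted, models[[j]]$fitted, labels,
                         alternative = "greater")$p_value)
  best <- c(deviance = tab$model[which.min(tab$deviance)],
            aic = tab$model[which.min(tab$aic)],
            bic = tab$model[which.min(tab$bic)],
            auc = tab$model[which.max(tab$auc)])
  structure(list(table = tab, p_auc = p, best = best),
            class = "lv_model_comparison")
}

#' @export
print.lv_model_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("best by criterion:",
      paste(names(x$best), x$best, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Group median shapes along the logistic-regression direction
#'
#' Combines the remodeling components into a single "logistic regression
#' score" direction using the standardized coefficients of a logistic model
#' fitted on the component scores, finds each group's median score, and
#' reconstructs the shape whose combined-component position sits at that
#' median.  This visualizes the shape contrast that best separates the
#' groups after covariate adjustment.
#'
#' @param decomp a [remodel_decompose()] fit.
#' @param model a [fit_logistic()] object whose feature block is the
#'   decomposition's score columns (same order).
#' @param labels 0/1 group labels aligned with the decomposition's subjects.
#' @param mean_shape base shape vector; defaults to the training mean.
#' @return List with `shapes` (one length-P raw shape vector per group,
#'   named by group label), `median_scores` (per-group median logistic
#'   regression score) and `subject_scores`.
#' @export
group_median_shape <- function(decomp, model, labels,
                               mean_shape = decomp$mean_shape) {
  K <- length(decomp$order)
  b <- model$table$coefficient[match(decomp$order, model$table$variable)]
  if (any(is.na(b)))
    stop("model does not contain coefficients for all components")
  # component block of the linear predictor = sum_i b_i * score_i
  subject_scores <- as.numeric(decomp$scores %*% b)
  groups <- sort(unique(labels))
  shapes <- list(); med <- numeric(0)
  sdsc <- apply(decomp$scores, 2, stats::sd)
  cstd <- b * sdsc  # standardized coefficients: the combination direction
  for (g in groups) {
    idx <- labels == g
    if (!any(idx)) stop("empty group: ", g)
    mg <- stats::median(subject_scores[idx])
    # weights along the standardized-coefficient direction reaching score mg
    alpha <- mg / sum(b * cstd)
    w <- alpha * cstd
    shapes[[as.character(g)]] <-
      mean_shape + as.numeric(decomp$components %*% w)
    med[as.character(g)] <- mg
  }
  list(shapes = shapes, median_scores = med,
       subject_scores = subject_scores)
}
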