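# Staged regularized logistic models.
#
# Stage 1 (lasso, L1): screens the wide one-hot design; the penalty drives
# the coefficients of uninformative features exactly to zero.
# Stage 2 (ridge, L2): refit on the lasso survivors only; every survivor
# keeps a finite nonzero coefficient whose magnitude supports ranking.
#
# Both stages minimize the glmnet objective
#   -(1/n) loglik(b0, beta) + lambda * [ alpha*||beta||_1 + (1-alpha)/2*||beta||_2^2 ]
# with the intercept unpenalized and no internal standardization (the design
# is already 0/1 indicators plus standardized numerics). Penalty strength is
# chosen by stratified K-fold cross-validation maximizing AUC.

#' Default penalty grid
#'
#' Log-spaced grid over `[1e-4, 1e2]`, descending (warm-start order).
#'
#' @param length_out Number of grid points.
#' @return Numeric vector of penalty strengths.
#' @export
lambda_grid_default <- function(length_out = 30L) {
  sort(10^seq(-4, 2, length.out = length_out), decreasing = TRUE)
}

# Stratified fold assignment: within each class, indices are shuffled under
# `seed` and dealt round-robin into folds, so every fold sees positives even
# at ~1% prevalence.
stratified_folds <- function(labels, k, seed) {
  labels <- as_binary_labels(labels)
  if (min(table(labels)) < k) {
    stop(sprintf("need at least %d observations per class for %d-fold CV", k, k))
  }
  foldid <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      foldid[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  foldid
}

fit_glmnet_stage <- function(x, y, alpha, lambda_grid, cv_folds, seed, stage) {
  y <- as_binary_labels(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 rows per class in training data")
  }
  if (is.null(colnames(x))) stop("design matrix must carry feature names")
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)

  zero_lambda <- length(lambda_grid) == 1L && lambda_grid == 0
  if (zero_lambda) {
    # Unregularized maximum likelihood; glmnet's path algorithm is not meant
    # for lambda = 0, so fall back to IRLS via glm.
    fit <- stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                          family = stats::binomial(),
                          control = list(epsilon = 1e-12, maxit = 100))
    if (!fit$converged) stop("unregularized logistic fit failed to converge")
    beta <- fit$coefficients[-1L]
    return(list(coefficients = beta, intercept = unname(fit$coefficients[1L]),
                lambda = 0, cv = NULL))
  }

  padded <- FALSE
  if (ncol(x) == 1L) {
    # glmnet requires >= 2 columns; a zero column is inert under the penalty
    x <- cbind(x, `..pad..` = 0)
    padded <- TRUE
  }
  path <- lambda_grid
  if (length(path) < 5L) {
    # pad with larger penalties so the coordinate-descent warm starts are
    # well conditioned even when a single target lambda is requested
    path <- sort(unique(c(path, max(path) * c(1000, 100, 10))), decreasing = TRUE)
  }
  cv_table <- NULL
  if (length(lambda_grid) > 1L) {
    foldid <- stratified_folds(y, cv_folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                               lambda = path, foldid = foldid,
                               type.measure = "auc",
                               standardize = FALSE, thresh = 1e-10)
    lambda <- cvfit$lambda.min # maximizes cross-validated AUC
    cv_table <- tibble::tibble(lambda = cvfit$lambda, cv_auc = cvfit$cvm)
  } else {
    lambda <- lambda_grid
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-12, maxit = 10^6)
  cf <- as.numeric(coef(fit, s = lambda, exact = TRUE, x = x, y = y))
  names(cf) <- rownames(coef(fit, s = lambda))
  beta <- cf[-1L]
  if (padded) beta <- beta[names(beta) != "..pad.."]
  if (any(!is.finite(beta))) {
    stop(sprintf("%s stage did not converge at lambda = %g", stage, lambda))
  }
  list(coefficients = beta, intercept = unname(cf[1L]), lambda = lambda,
       cv = cv_table)
}

#' Fit the lasso (L1-regularized) logistic screening model
#'
#' @param x Numeric design matrix with column names (rows = respondents).
#' @param y Binary labels aligned with `x`; both classes required.
#' @param lambda_grid Candidate penalty strengths. A single value skips
#'   cross-validation; `0` requests the unregularized maximum-likelihood fit.
#' @param cv_folds Number of stratified CV folds.
#' @param seed Integer seed controlling the fold assignment.
#' @param nonzero_tol Coefficients with `|beta| <= nonzero_tol` are treated
#'   as exactly zero by [nonzero_features()].
#' @return Object of class `lasso_fit`: `coefficients` (named), `intercept`,
#'   `lambda`, `nonzero_tol`, and the CV curve (`cv`) when a grid was searched.
#' @export
fit_l1_logistic <- function(x, y, lambda_grid = lambda_grid_default(),
                            cv_folds = 5L, seed = 1L, nonzero_tol = 1e-8) {
  out <- fit_glmnet_stage(x, y, alpha = 1, lambda_grid, cv_folds, seed, "lasso")
  out$nonzero_tol <- nonzero_tol
  class(out) <- "lasso_fit"
  out
}

#' Features surviving the lasso stage
#'
#' @param fit A [lasso_fit].
#' @return Character vector of features with `|coefficient| > nonzero_tol`
#'   (strict inequality), in design order.
#' @export
nonzero_features <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  keep <- names(fit$coefficients)[abs(fit$coefficients) > fit$nonzero_tol]
  if (length(keep) == 0L) {
    stop("lasso zeroed every coefficient; decrease the penalty (lambda_grid)")
  }
  keep
}

#' Fit the ridge (L2-regularized) logistic ranking model
#'
#' Intended to run on the design restricted to [nonzero_features()] of the
#' lasso stage.
#'
#' @inheritParams fit_l1_logistic
#' @param lambda A fixed penalty, or `NULL` to choose it by stratified CV
#'   over `lambda_grid`.
#' @return Object of class `ridge_fit` (same fields as `lasso_fit`).
#' @export
fit_l2_logistic <- function(x, y, lambda = NULL,
                            lambda_grid = lambda_grid_default(),
                            cv_folds = 5L, seed = 1L) {
  grid <- if (is.null(lambda)) lambda_grid else lambda
  out <- fit_glmnet_stage(x, y, alpha = 0, grid, cv_folds, seed, "ridge")
  class(out) <- "ridge_fit"
  out
}

#' Predicted outcome probabilities from a regularized fit
#'
#' @param fit A `lasso_fit` or `ridge_fit`.
#' @param x Design matrix containing (at least) the fit's features.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, c("lasso_fit", "ridge_fit")))
  feats <- names(fit$coefficients)
  missing <- setdiff(feats, colnames(x))
  if (length(missing) > 0L) {
    stop("design lacks fitted features: ", paste(head(missing, 5), collapse = ", "))
  }
  eta <- drop(x[, feats, drop = FALSE] %*% fit$coefficients) + fit$intercept
  plogis(eta)
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(abs(x$coefficients) > x$nonzero_tol)
  cat(sprintf("Lasso logistic fit: %d/%d nonzero features at lambda = %.4g\n",
              nz, length(x$coefficients), x$lambda))
  invisible(x)
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge logistic fit: %d features at lambda = %.4g\n",
              length(x$coefficients), x$lambda))
  invisible(x)
}
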