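# Independent oracles: deliberately naive implementations used only to
# check the package's fast paths.

# AUC by exhaustive enumeration of (positive, negative) pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Discrete curvature at every interior rank, by explicit loop.
curvature_oracle <- function(y) {
  p <- length(y)
  kappa <- rep(NA_real_, p)
  for (i in 2:(p - 1)) {
    d1 <- (y[i + 1] - y[i - 1]) / 2
    d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
    kappa[i] <- abs(d2) / (1 + d1^2)^1.5
  }
  k <- kappa[2:(p - 1)]
  list(kappa = kappa,
       degenerate = max(k) < 1e-12,
       knee = if (max(k) < 1e-12) NA_integer_ else (2:(p - 1))[which.max(k)])
}

# Unpenalized logistic MLE by iteratively reweighted least squares.
irls_logistic <- function(x, y, iters = 100, tol = 1e-12) {
  X <- cbind(1, x)
  b <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, W * X), crossprod(X, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# L1-penalized logistic regression by proximal gradient descent on
# -(1/n) loglik + lambda * ||beta||_1, intercept unpenalized.
prox_lasso_oracle <- function(x, y, lambda, iters = 2e5, tol = 1e-13) {
  n <- nrow(x)
  X <- cbind(1, x)
  L <- max(eigen(crossprod(X) / (4 * n), symmetric = TRUE,
                 only.values = TRUE)$values)
  step <- 1 / L
  b <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    grad <- crossprod(X, plogis(drop(X %*% b)) - y) / n
    bn <- b - step * grad
    bn[-1] <- sign(bn[-1]) * pmax(abs(bn[-1]) - step * lambda, 0)
    if (max(abs(bn - b)) < tol) {
      b <- bn
      break
    }
    b <- bn
  }
  list(intercept = b[1], beta = b[-1])
}

# L2-penalized logistic regression by direct BFGS minimization of
# -(1/n) loglik + (lambda/2) * ||beta||_2^2, intercept unpenalized.
ridge_oracle <- function(x, y, lambda) {
  n <- nrow(x)
  X <- cbind(1, x)
  obj <- function(par) {
    eta <- drop(X %*% par)
    -mean(y * eta - log1p(exp(eta))) + lambda / 2 * sum(par[-1]^2)
  }
  gr <- function(par) {
    eta <- drop(X %*% par)
    g <- -crossprod(X, y - plogis(eta)) / n
    g[-1] <- g[-1] + lambda * par[-1]
    drop(g)
  }
  o <- optim(rep(0, ncol(X)), obj, gr, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 5000))
  list(intercept = o$par[1], beta = o$par[-1])
}

# Cramer's V between two categorical vectors.
cramers_v <- function(a, b) {
  tab <- table(a, b)
  chi2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  unname(sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}
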