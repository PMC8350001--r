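# Feed-forward neural cross-check.
#
# A second, independent route to the correlates: lasso pre-filters the wide
# design, a small feed-forward network with tanh activations and batch
# normalization is trained on the survivors, per-feature importances are
# scored by permutation on the test split, and the knee-point rule cuts the
# importance curve exactly as it cuts the ridge coefficient curve.
#
# The network is implemented directly with matrix algebra (dense layers,
# batch-norm, tanh, minibatch gradient training) so that training is fully
# deterministic given the seed.

#' Neural network configuration
#'
#' @param hidden Integer vector of hidden-layer unit counts.
#' @param batch_norm Apply batch normalization after each hidden affine
#'   layer (before the tanh).
#' @param epochs Training epochs (default 100).
#' @param batch_size Minibatch size (default 100).
#' @param learning_rate Fixed step size (default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`; both use the fixed step.
#' @param seed Integer seed controlling initialization and batch order.
#' @return List of class `nn_config`.
#' @export
nn_config <- function(hidden = c(64L, 32L), batch_norm = TRUE,
                      epochs = 100L, batch_size = 100L,
                      learning_rate = 1e-3,
                      optimizer = c("adam", "sgd"), seed = 1L) {
  stopifnot(all(hidden >= 1L), epochs >= 1L, batch_size >= 1L,
            learning_rate > 0)
  structure(list(hidden = as.integer(hidden), batch_norm = batch_norm,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = match.arg(optimizer), seed = as.integer(seed)),
            class = "nn_config")
}

init_params <- function(p_in, hidden) {
  sizes <- c(p_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out)) # Glorot uniform, suits tanh
    list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out),
      gamma = rep(1, fan_out), beta = rep(0, fan_out),
      run_mean = rep(0, fan_out), run_var = rep(1, fan_out)
    )
  })
}

# Forward pass. `train = TRUE` uses batch statistics (and caches what the
# backward pass needs); inference uses running statistics.
nn_forward <- function(params, x, batch_norm, train = FALSE, momentum = 0.1) {
  L <- length(params)
  cache <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    pl <- params[[l]]
    z <- sweep(a %*% pl$W, 2, pl$b, "+")
    hidden_layer <- l < L
    if (batch_norm && hidden_layer) {
      if (train) {
        mu <- colMeans(z)
        v <- colMeans(sweep(z, 2, mu)^2) # population variance of the batch
        params[[l]]$run_mean <- (1 - momentum) * pl$run_mean + momentum * mu
        params[[l]]$run_var <- (1 - momentum) * pl$run_var + momentum * v
      } else {
        mu <- pl$run_mean
        v <- pl$run_var
      }
      zhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + 1e-8), "/")
      zt <- sweep(sweep(zhat, 2, pl$gamma, "*"), 2, pl$beta, "+")
    } else {
      mu <- NULL; v <- NULL; zhat <- NULL; zt <- z
    }
    h <- tanh(zt)
    cache[[l]] <- list(a_in = a, z = z, mu = mu, v = v, zhat = zhat, h = h)
    a <- h
  }
  score <- (a + 1) / 2 # tanh output affinely mapped to [0, 1]
  list(score = drop(score), cache = cache, params = params)
}

# Backward pass: binary cross-entropy on the mapped score.
nn_backward <- function(params, cache, y, batch_norm) {
  L <- length(params)
  n <- length(y)
  eps <- 1e-7
  s <- pmin(pmax((cache[[L]]$h + 1) / 2, eps), 1 - eps)
  # dL/ds for mean BCE, then ds/dh = 1/2
  dh <- matrix(((s - y) / (s * (1 - s))) / n * 0.5, ncol = 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cl <- cache[[l]]
    dzt <- dh * (1 - cl$h^2) # through tanh
    hidden_layer <- l < L
    if (batch_norm && hidden_layer) {
      m <- nrow(dzt)
      dgamma <- colSums(dzt * cl$zhat)
      dbeta <- colSums(dzt)
      inv_sd <- 1 / sqrt(cl$v + 1e-8)
      dzhat <- sweep(dzt, 2, params[[l]]$gamma, "*")
      # standard batch-norm backward
      dz <- sweep(
        dzhat - matrix(colMeans(dzhat), m, ncol(dzhat), byrow = TRUE) -
          sweep(cl$zhat, 2, colMeans(dzhat * cl$zhat), "*"),
        2, inv_sd, "*")
    } else {
      dgamma <- NULL; dbeta <- NULL
      dz <- dzt
    }
    grads[[l]] <- list(W = crossprod(cl$a_in, dz), b = colSums(dz),
                       gamma = dgamma, beta = dbeta)
    if (l > 1L) dh <- dz %*% t(params[[l]]$W)
  }
  grads
}

nn_loss <- function(scores, y) {
  eps <- 1e-7
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

#' Train the feed-forward network
#'
#' Intended to run on the design restricted to the lasso-surviving features
#' ([nonzero_features()]); [nn_pipeline()] wires the two stages together.
#'
#' @param x Numeric design matrix (training rows only) with column names.
#' @param y Binary labels aligned with `x`.
#' @param config An [nn_config].
#' @return Object of class `nn_model`: fitted parameters, the config, the
#'   feature names, and the per-epoch mean training loss (`loss_history`).
#' @export
fit_feedforward <- function(x, y, config = nn_config()) {
  y <- as_binary_labels(y)
  stopifnot(is.matrix(x), nrow(x) == length(y), inherits(config, "nn_config"))
  if (is.null(colnames(x))) stop("design matrix must carry feature names")
  assert_both_classes(y, "fit_feedforward()")
  n <- nrow(x)

  with_seed(config$seed, {
    params <- init_params(ncol(x), config$hidden)
    opt <- if (config$optimizer == "adam") adam_state(params) else NULL
    step <- 0L
    loss_history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0; epoch_n <- 0L
      for (st in starts) {
        idx <- perm[st:min(st + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next # batch-norm needs >= 2 rows
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- nn_forward(params, xb, config$batch_norm, train = TRUE)
        params <- fw$params # running batch-norm statistics updated
        loss <- nn_loss(fw$score, yb)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        epoch_n <- epoch_n + length(idx)
        grads <- nn_backward(params, fw$cache, yb, config$batch_norm)
        step <- step + 1L
        if (config$optimizer == "adam") {
          upd <- adam_update(params, grads, opt, config$learning_rate, step)
          params <- upd$params; opt <- upd$state
        } else {
          params <- sgd_update(params, grads, config$learning_rate)
        }
      }
      loss_history[epoch] <- epoch_loss / epoch_n
    }
    structure(list(params = params, config = config,
                   feature_names = colnames(x),
                   loss_history = loss_history),
              class = "nn_model")
  })
}

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

adam_state <- function(params) {
  lapply(params, function(pl) {
    lapply(setNames(PARAM_FIELDS, PARAM_FIELDS), function(f) {
      list(m = pl[[f]] * 0, v = pl[[f]] * 0)
    })
  })
}

adam_update <- function(params, grads, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    for (f in PARAM_FIELDS) {
      g <- grads[[l]][[f]]
      if (is.null(g)) next
      st <- state[[l]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^step)
      vhat <- st$v / (1 - beta2^step)
      params[[l]][[f]] <- params[[l]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[f]] <- st
    }
  }
  list(params = params, state = state)
}

sgd_update <- function(params, grads, lr) {
  for (l in seq_along(params)) {
    for (f in PARAM_FIELDS) {
      if (is.null(grads[[l]][[f]])) next
      params[[l]][[f]] <- params[[l]][[f]] - lr * grads[[l]][[f]]
    }
  }
  params
}

#' Predict scores from a fitted network
#'
#' @param object An `nn_model`.
#' @param newdata Design matrix containing the model's features.
#' @param ... Unused.
#' @return Scores in `[0, 1]` (inference mode: running batch-norm
#'   statistics).
#' @export
predict.nn_model <- function(object, newdata, ...) {
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing) > 0L) {
    stop("design lacks fitted features: ", paste(head(missing, 5), collapse = ", "))
  }
  x <- newdata[, object$feature_names, drop = FALSE]
  nn_forward(object$params, x, object$config$batch_norm, train = FALSE)$score
}

#' Permutation feature importance on the test split
#'
#' Importance of a feature = mean drop in test AUC over `n_repeats`
#' independent shuffles of that feature's column (other columns held
#' fixed). A feature the model ignores scores ~0.
#'
#' @param model An `nn_model`.
#' @param x_test Test design matrix (>= 30 rows).
#' @param y_test Test labels; both classes required.
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Integer seed making the shuffles reproducible.
#' @return Tibble of class `importance_ranking` with columns `rank`,
#'   `feature`, `importance`, sorted by non-increasing importance (ties
#'   broken lexicographically), with attribute `base_auc` and
#'   `method = "permutation"`.
#' @export
nn_feature_importance <- function(model, x_test, y_test, n_repeats = 10L,
                                  seed = 1L) {
  stopifnot(inherits(model, "nn_model"), is.matrix(x_test))
  y_test <- as_binary_labels(y_test)
  if (nrow(x_test) < 30L) stop("permutation importance needs >= 30 test rows")
  assert_both_classes(y_test, "nn_feature_importance()")
  x <- x_test[, model$feature_names, drop = FALSE]
  base_auc <- auc(predict(model, x), y_test)
  imp <- with_seed(seed, {
    vapply(seq_along(model$feature_names), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample(nrow(xp)), j]
        base_auc - auc(predict(model, xp), y_test)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  ord <- order(-imp, model$feature_names)
  out <- tibble::tibble(rank = seq_along(imp),
                        feature = model$feature_names[ord],
                        importance = imp[ord])
  attr(out, "base_auc") <- base_auc
  attr(out, "method") <- "permutation"
  class(out) <- c("importance_ranking", class(out))
  out
}

#' First-layer weight-norm importance (alternative scoring)
#'
#' L2 norm of each feature's outgoing first-layer weights; a cheap
#' model-internal alternative to permutation importance.
#'
#' @param model An `nn_model`.
#' @return An `importance_ranking` (attribute `method = "first_layer_norm"`).
#' @export
nn_first_layer_importance <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  W <- model$params[[1L]]$W
  imp <- sqrt(rowSums(W^2))
  ord <- order(-imp, model$feature_names)
  out <- tibble::tibble(rank = seq_along(imp),
                        feature = model$feature_names[ord],
                        importance = imp[ord])
  attr(out, "method") <- "first_layer_norm"
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Knee-point selection on the importance curve
#'
#' Applies the same maximum-curvature rule used on the ridge coefficient
#' curve to the sorted importance scores.
#'
#' @param importances An `importance_ranking` (>= 4 features).
#' @param ... Passed to [knee_point()].
#' @return A `knee_selection`.
#' @export
nn_select_features <- function(importances, ...) {
  stopifnot(inherits(importances, "importance_ranking"))
  if (nrow(importances) < 4L) stop("knee detection needs >= 4 ranked features")
  y <- setNames(importances$importance, importances$feature)
  knee_point(y, ...)
}

#' Lasso-prefiltered neural pipeline
#'
#' The full second-route analysis: lasso screens the design on the training
#' split, the network trains on the surviving features, permutation
#' importances are scored on the test split, and the knee rule selects the
#' reported features.
#'
#' @param design An [encoded_design].
#' @param labels Binary outcome labels aligned with the design rows.
#' @param split A [split_indices].
#' @param config An [nn_config].
#' @param lambda_grid,cv_folds Lasso penalty search (as in
#'   [fit_l1_logistic()]).
#' @param n_repeats Permutation repeats for the importance scores.
#' @param seed Seed for the lasso CV folds and the permutations.
#' @return List with `model`, `importance`, `selection` (a
#'   `knee_selection`), `lasso_features`, and test `metrics`.
#' @export
nn_pipeline <- function(design, labels, split, config = nn_config(),
                        lambda_grid = lambda_grid_default(), cv_folds = 5L,
                        n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(design, "encoded_design"),
            inherits(split, "split_indices"))
  labels <- as_binary_labels(labels)
  xtr <- design$matrix[split$train_idx, , drop = FALSE]
  xte <- design$matrix[split$test_idx, , drop = FALSE]
  ytr <- labels[split$train_idx]
  yte <- labels[split$test_idx]
  lasso <- fit_l1_logistic(xtr, ytr, lambda_grid = lambda_grid,
                           cv_folds = cv_folds, seed = seed)
  keep <- nonzero_features(lasso)
  model <- fit_feedforward(xtr[, keep, drop = FALSE], ytr, config)
  importance <- nn_feature_importance(model, xte[, keep, drop = FALSE], yte,
                                      n_repeats = n_repeats,
                                      seed = derive_seed(seed, 2L))
  selection <- if (length(keep) >= 4L) {
    nn_select_features(importance)
  } else {
    structure(list(knee_index = NA_integer_, knee_value = NA_real_,
                   curvature = rep(NA_real_, length(keep)),
                   selected = keep, degenerate = TRUE),
              class = "knee_selection")
  }
  metrics <- classification_metrics(predict(model, xte), yte)
  list(model = model, importance = importance, selection = selection,
       lasso_features = keep, metrics = metrics)
}
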