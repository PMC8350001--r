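# Knee-point selection on a ranked coefficient curve.
#
# After the ridge stage, features are sorted by |coefficient| and the sorted
# magnitudes y_1 >= y_2 >= ... >= y_p are treated as a discrete curve over
# ranks x = 1..p. The knee (elbow) is the rank of maximum discrete curvature
#   kappa_i = |y''_i| / (1 + y'_i^2)^(3/2)
# with y' and y'' the central first and second differences at interior ranks.
# Features whose magnitude lies strictly above the magnitude at the knee are
# retained.

#' Rank ridge coefficients by magnitude
#'
#' @param fit A [ridge_fit] (or any object with a named `coefficients`
#'   vector), or a named numeric vector of coefficients.
#' @param signed If `TRUE`, rank by signed coefficient value instead of
#'   absolute magnitude (discards strong protective factors from the top of
#'   the curve; the default absolute ranking keeps risk and protective
#'   correlates together).
#' @return A tibble of class `coefficient_ranking` with columns `rank`,
#'   `feature`, `coefficient`, `magnitude`, sorted by non-increasing
#'   magnitude (ties broken lexicographically by feature name).
#' @export
rank_coefficients <- function(fit, signed = FALSE) {
  beta <- if (is.numeric(fit)) fit else fit$coefficients
  if (length(beta) < 1L) stop("at least one coefficient is required")
  if (is.null(names(beta)) || anyDuplicated(names(beta))) {
    stop("coefficients must carry unique feature names")
  }
  if (any(!is.finite(beta))) stop("coefficients must be finite")
  magnitude <- if (signed) beta else abs(beta)
  ord <- order(-magnitude, names(beta))
  out <- tibble::tibble(
    rank = seq_along(beta),
    feature = names(beta)[ord],
    coefficient = unname(beta[ord]),
    magnitude = unname(magnitude[ord])
  )
  class(out) <- c("coefficient_ranking", class(out))
  out
}

#' Knee point of a ranked curve by maximum discrete curvature
#'
#' @param ranking A `coefficient_ranking` (from [rank_coefficients()]) or a
#'   named numeric vector of non-increasing curve values (e.g. permutation
#'   importances sorted descending).
#' @param smoothing_window Odd integer; width of a centered moving average
#'   applied to the curve before differencing. `1` (the default) means no
#'   smoothing: curvature is computed on the raw ranked values.
#' @param inclusive If `FALSE` (default), select features with curve value
#'   strictly greater than the value at the knee rank (the knee feature and
#'   any ties with it are excluded). If `TRUE`, select the rank prefix up to
#'   and including the knee.
#' @param degenerate_tol Curvature below this everywhere means the curve is
#'   (near) linear and carries no knee; all features are selected and the
#'   result is flagged `degenerate`.
#' @return List of class `knee_selection`: `knee_index`, `knee_value`,
#'   `curvature` (length p, `NA` at the two boundary ranks), `selected`
#'   (character vector, always a prefix of the ranking), `degenerate`.
#' @export
knee_point <- function(ranking, smoothing_window = 1L, inclusive = FALSE,
                       degenerate_tol = 1e-12) {
  if (inherits(ranking, "coefficient_ranking")) {
    y <- ranking$magnitude
    features <- ranking$feature
  } else if (is.numeric(ranking)) {
    y <- unname(ranking)
    features <- names(ranking) %||% as.character(seq_along(ranking))
  } else {
    stop("ranking must be a coefficient_ranking or a named numeric vector")
  }
  p <- length(y)
  if (p < 4L) stop("knee detection needs a ranking of length >= 4")
  if (any(diff(y) > 1e-9)) stop("curve values must be non-increasing")
  stopifnot(smoothing_window >= 1L, smoothing_window %% 2L == 1L)

  ys <- moving_average(y, smoothing_window)
  i <- 2:(p - 1)
  d1 <- (ys[i + 1L] - ys[i - 1L]) / 2
  d2 <- ys[i + 1L] - 2 * ys[i] + ys[i - 1L]
  kappa <- abs(d2) / (1 + d1^2)^1.5
  curvature <- c(NA_real_, kappa, NA_real_)

  if (max(kappa) < degenerate_tol) {
    out <- list(knee_index = NA_integer_, knee_value = NA_real_,
                curvature = curvature, selected = features,
                degenerate = TRUE)
    class(out) <- "knee_selection"
    return(out)
  }
  knee_index <- i[which.max(kappa)] # which.max -> earliest on ties
  selected <- if (inclusive) {
    features[seq_len(knee_index)]
  } else {
    features[y > y[knee_index]] # strict; ties at the knee value excluded
  }
  out <- list(knee_index = knee_index, knee_value = y[knee_index],
              curvature = curvature, selected = selected, degenerate = FALSE)
  class(out) <- "knee_selection"
  out
}

# Centered moving average with shrinking windows at the boundaries, so no
# rank is lost to edge effects.
moving_average <- function(y, window) {
  if (window == 1L) return(y)
  half <- (window - 1L) %/% 2L
  p <- length(y)
  vapply(seq_len(p), function(j) {
    lo <- max(1L, j - half)
    hi <- min(p, j + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' @export
print.knee_selection <- function(x, ...) {
  if (x$degenerate) {
    cat("Knee selection: degenerate (near-linear) curve; all",
        length(x$selected), "features selected\n")
  } else {
    cat(sprintf("Knee at rank %d (value %.6g); %d feature(s) above the knee\n",
                x$knee_index, x$knee_value, length(x$selected)))
  }
  invisible(x)
}
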