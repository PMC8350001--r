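# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All exported stochastic operations route through
# this so that a single integer seed makes them reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a base seed and an offset, kept inside the 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1000003 * as.double(offset)) %% 2147483647L)
}

# Coerce labels to an integer 0/1 vector; accepts logical, numeric 0/1, or a
# two-level factor (second level = positive).
as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) > 2L) stop("labels must have at most two levels")
    labels <- as.integer(labels) - 1L
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || !all(labels[!is.na(labels)] %in% c(0, 1))) {
    stop("labels must be binary (0/1, logical, or a two-level factor)")
  }
  as.integer(labels)
}

assert_both_classes <- function(labels, context = "input") {
  labels <- labels[!is.na(labels)]
  if (length(unique(labels)) < 2L) {
    stop(sprintf("both outcome classes must be present in %s", context))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Percentage from supplied counts
#'
#' Tiny convenience used in descriptive summaries and report tables:
#' `100 * numerator / denominator`. Denominators of zero are an error rather
#' than `NaN` so that empty subgroups are caught early.
#'
#' @param numerator,denominator Non-negative counts.
#' @return The rate as a percentage in `[0, 100]` (unrounded).
#' @examples
#' derived_rate(601509, 616346) # household response rate, percent
#' @export
derived_rate <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  100 * numerator / denominator
}
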