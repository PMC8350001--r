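# Synthetic wide-survey generator.
#
# The real study data (a national demographic and health survey) are
# registration-restricted, so the pipeline is validated on synthetic tables
# that emulate their structure: tens of thousands of rows, many categorical
# variables that explode into one-hot features, a rare binary outcome, and
# features correlated within analyst-meaningful themes.
#
# Signal is planted at the theme level: each theme t carries a latent
# standard-normal factor z_t per respondent; every variable in the theme is
# a quantile-binned categorical of rho*z_t + sqrt(1-rho^2)*noise (so its
# marginal stays standard normal and the bins are balanced), and the outcome
# is Bernoulli(logistic(b0 + sum_t beta_t z_t)) with b0 calibrated to a
# target prevalence.

#' Configure the synthetic survey generator
#'
#' @param n_rows Number of respondents.
#' @param themes Data frame with columns `name`, `n_variables`,
#'   `n_categories`, `rho` (within-theme latent loading in `[0, 1)`).
#' @param informative_effects Named numeric vector of log-odds effects per
#'   latent unit; names must be a subset of `themes$name`. Themes absent
#'   from it carry no signal.
#' @param target_prevalence Desired outcome prevalence in (0, 1).
#' @param missing_rate Probability that any predictor cell is missing
#'   (completely at random).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows, themes, informative_effects = numeric(),
                             target_prevalence = 0.02, missing_rate = 0,
                             seed = 1L) {
  themes <- tibble::as_tibble(themes)
  stopifnot(all(c("name", "n_variables", "n_categories", "rho") %in% names(themes)),
            n_rows >= 1, !anyDuplicated(themes$name),
            all(themes$n_variables >= 1), all(themes$n_categories >= 2),
            all(themes$rho >= 0 & themes$rho < 1),
            target_prevalence > 0, target_prevalence < 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(informative_effects) > 0L &&
      !all(names(informative_effects) %in% themes$name)) {
    stop("informative_effects names must be a subset of themes$name")
  }
  structure(list(n_rows = as.integer(n_rows), themes = themes,
                 informative_effects = informative_effects,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' The reference end-to-end validation scenario (S1)
#'
#' 20,000 respondents; 10 themes of 10 three-category variables each
#' (latent loading rho = 0.6); themes 1-3 informative with effect 0.8
#' log-odds per latent unit; outcome prevalence 2%; no missingness; seed 7.
#'
#' @param seed Generator seed (default 7).
#' @return A [synthetic_config].
#' @export
synthetic_config_s1 <- function(seed = 7L) {
  themes <- tibble::tibble(
    name = sprintf("theme%02d", 1:10),
    n_variables = 10L, n_categories = 3L, rho = 0.6
  )
  synthetic_config(
    n_rows = 20000L, themes = themes,
    informative_effects = setNames(rep(0.8, 3), themes$name[1:3]),
    target_prevalence = 0.02, missing_rate = 0, seed = seed
  )
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Bisection on the intercept `b0` until the Monte-Carlo mean of
#' `logistic(b0 + sum_t beta_t z_t)` (z_t iid standard normal) is within
#' `tol` of the target.
#'
#' @param target_prevalence Target mean outcome probability in (0, 1).
#' @param effects Numeric vector of theme effects (possibly empty).
#' @param n_mc Monte-Carlo sample size (>= 10,000).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param tol Convergence tolerance on the achieved mean probability.
#' @return The calibrated intercept `b0`.
#' @export
solve_intercept <- function(target_prevalence, effects = numeric(),
                            n_mc = 1e5, seed = 1L, tol = 1e-4) {
  stopifnot(target_prevalence > 0, target_prevalence < 1, n_mc >= 1e4)
  s <- sqrt(sum(effects^2))
  if (s == 0) return(qlogis_safe(target_prevalence))
  g <- with_seed(seed, rnorm(n_mc, 0, s))
  f <- function(b0) mean(plogis(b0 + g)) - target_prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("no intercept bracket within [-30, 30]")
  repeat {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol || (hi - lo) < 1e-12) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
}

qlogis_safe <- function(p) log(p / (1 - p))

#' Generate a synthetic wide survey with planted themed signal
#'
#' @param config A [synthetic_config].
#' @return List with:
#'   * `table` — a [survey_table] of categorical variables named
#'     `<theme>_v<j>` with levels `c1..cK`;
#'   * `truth` — ground truth for recovery tests: `labels` (the drawn
#'     outcome), `probabilities`, `intercept`, `effects`,
#'     `informative_themes`, `informative_variables`, `latent` matrix;
#'   * `theme_map` — the generating variable-to-theme assignment, directly
#'     usable by the ITA engine.
#' @export
generate_wide_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  th <- config$themes
  n <- config$n_rows
  beta <- setNames(rep(0, nrow(th)), th$name)
  beta[names(config$informative_effects)] <- config$informative_effects
  b0 <- solve_intercept(config$target_prevalence, config$informative_effects,
                        seed = derive_seed(config$seed, 1L))

  out <- with_seed(config$seed, {
    z <- matrix(rnorm(n * nrow(th)), n, nrow(th),
                dimnames = list(NULL, th$name))
    cols <- list()
    for (t in seq_len(nrow(th))) {
      k <- th$n_categories[t]
      cuts <- qnorm(seq_len(k - 1L) / k) # balanced bins of a N(0,1) marginal
      for (j in seq_len(th$n_variables[t])) {
        u <- th$rho[t] * z[, t] + sqrt(1 - th$rho[t]^2) * rnorm(n)
        nm <- sprintf("%s_v%02d", th$name[t], j)
        cols[[nm]] <- paste0("c", findInterval(u, cuts) + 1L)
      }
    }
    eta <- b0 + drop(z %*% beta)
    prob <- plogis(eta)
    labels <- rbinom(n, 1L, prob)
    if (config$missing_rate > 0) {
      for (nm in names(cols)) {
        hit <- runif(n) < config$missing_rate
        cols[[nm]][hit] <- NA_character_
      }
    }
    list(cols = cols, z = z, prob = prob, labels = labels)
  })

  schema <- survey_schema(setNames(as.list(rep("categorical",
                                               length(out$cols))),
                                   names(out$cols)))
  table <- survey_table(tibble::as_tibble(out$cols), schema)
  theme_map <- setNames(
    lapply(rep(th$name, th$n_variables), identity),
    names(out$cols)
  )
  informative <- names(config$informative_effects)
  truth <- list(
    labels = out$labels,
    probabilities = out$prob,
    intercept = b0,
    effects = beta,
    informative_themes = informative,
    informative_variables = names(theme_map)[
      vapply(theme_map, function(t) any(t %in% informative), logical(1))],
    latent = out$z
  )
  list(table = table, truth = truth, theme_map = theme_map)
}

#' Micro-fixture exercising the NMSV outcome rule
#'
#' Builds a small survey table covering all four label cases with known
#' counts: no violence; violence with husband as the only perpetrator
#' (labelled no); violence by a non-husband perpetrator (labelled yes);
#' violence by husband plus another perpetrator (labelled yes).
#'
#' @param seed Seed controlling the row shuffle.
#' @param counts Named integer vector with entries `none`, `husband_only`,
#'   `nonhusband`, `husband_plus`.
#' @return List with `table` (a [survey_table]), `spec` (the matching
#'   [outcome_spec]), and `expected_labels` (aligned with the table rows).
#' @export
generate_nmsv_fixture <- function(seed = 1L,
                                  counts = c(none = 10L, husband_only = 10L,
                                             nonhusband = 5L,
                                             husband_plus = 5L)) {
  stopifnot(all(c("none", "husband_only", "nonhusband", "husband_plus") %in%
                  names(counts)), all(counts >= 0), sum(counts) >= 1)
  row <- function(flag, husband, stranger, relative, label) {
    data.frame(ever_forced_sex = flag, perp_husband = husband,
               perp_stranger = stranger, perp_relative = relative,
               label = label)
  }
  blocks <- list(
    do.call(rbind, rep(list(row(0L, 0L, 0L, 0L, 0L)), counts[["none"]])),
    do.call(rbind, rep(list(row(1L, 1L, 0L, 0L, 0L)), counts[["husband_only"]])),
    do.call(rbind, rep(list(row(1L, 0L, 1L, 0L, 1L)), counts[["nonhusband"]])),
    do.call(rbind, rep(list(row(1L, 1L, 0L, 1L, 1L)), counts[["husband_plus"]]))
  )
  df <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  perm <- with_seed(seed, sample(nrow(df)))
  df <- df[perm, , drop = FALSE]
  labels <- df$label
  df$label <- NULL
  schema <- survey_schema(list(
    ever_forced_sex = "binary", perp_husband = "binary",
    perp_stranger = "binary", perp_relative = "binary"
  ))
  list(
    table = survey_table(df, schema),
    spec = outcome_spec("ever_forced_sex",
                        c("perp_husband", "perp_stranger", "perp_relative"),
                        husband_codes = "perp_husband"),
    expected_labels = labels
  )
}
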