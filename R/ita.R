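# Iterative thematic analysis (ITA).
#
# Each iteration fits lasso -> ridge on the current design, ranks the ridge
# coefficients, cuts the ranked curve at the knee, groups the selected
# features into analyst-declared themes (a theme "qualifies" when it holds
# at least 5% of the selected features), records metrics, checks the
# stopping rules, and — if continuing — drops the dominant qualifying
# theme's selected features from all later iterations. The declarative
# theme map stands in for the study's two-coder qualitative step.

#' Read a theme map
#'
#' YAML (`variable: theme` or `variable: [theme1, theme2]`) or TSV with two
#' columns, variable and comma-separated themes. A variable may map to
#' multiple themes.
#'
#' @param path Path to the file; format inferred from the extension
#'   (`.yml`/`.yaml` vs anything else = TSV).
#' @return Named list: variable -> character vector of themes.
#' @export
read_theme_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    tm <- lapply(raw, as.character)
  } else {
    df <- read.csv(path, sep = "\t", colClasses = "character",
                   check.names = FALSE)
    if (ncol(df) < 2L) stop("theme map TSV needs columns: variable, themes")
    tm <- setNames(lapply(df[[2L]], function(s) {
      trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    }), df[[1L]])
  }
  validate_theme_map(tm)
}

validate_theme_map <- function(theme_map) {
  if (!is.list(theme_map) || length(theme_map) == 0L ||
      is.null(names(theme_map))) {
    stop("theme map must be a non-empty named list: variable -> themes")
  }
  if (any(vapply(theme_map, function(t) any(!nzchar(t)) || length(t) == 0L,
                 logical(1)))) {
    stop("every variable must map to at least one non-empty theme name")
  }
  theme_map
}

#' Percent agreement between two theme maps
#'
#' Mirrors the inter-coder reliability check of a two-coder qualitative
#' step: the percentage of variables (in the union of the two maps) whose
#' theme sets are identical.
#'
#' @param map_a,map_b Theme maps (named lists, as from [read_theme_map()]).
#' @return Agreement percentage in `[0, 100]`.
#' @export
theme_map_agreement <- function(map_a, map_b) {
  validate_theme_map(map_a); validate_theme_map(map_b)
  vars <- union(names(map_a), names(map_b))
  same <- vapply(vars, function(v) {
    setequal(map_a[[v]] %||% character(), map_b[[v]] %||% character())
  }, logical(1))
  derived_rate(sum(same), length(vars))
}

#' Group selected features into themes and test qualification
#'
#' Membership is computed on source variables via the encoding provenance;
#' a variable mapped to several themes counts in each. A theme qualifies
#' when its member count is at least `ceiling(min_fraction * n_selected)`.
#' Features whose source variable is absent from the map are collected in
#' an `"<uncategorized>"` bucket, reported but never qualifying.
#'
#' @param selected Character vector of selected features (e.g.
#'   `knee$selected`), or a `knee_selection`.
#' @param theme_map Named list variable -> themes.
#' @param provenance Provenance tibble from the [encoded_design]
#'   (columns `feature`, `variable`).
#' @param ranking Optional `coefficient_ranking` supplying coefficient
#'   magnitudes for `coefficient_mass`.
#' @param min_fraction Qualification threshold as a fraction of the number
#'   of selected features (default 0.05).
#' @return Tibble of class `theme_summary`: `theme`, `n_members`,
#'   `members` (list column), `coefficient_mass`, `qualifies`.
#' @export
assign_themes <- function(selected, theme_map, provenance, ranking = NULL,
                          min_fraction = 0.05) {
  if (inherits(selected, "knee_selection")) selected <- selected$selected
  stopifnot(is.character(selected), length(selected) >= 1L)
  validate_theme_map(theme_map)
  var_of <- setNames(provenance$variable, provenance$feature)
  if (any(!selected %in% names(var_of))) {
    stop("selected feature(s) missing from provenance")
  }
  mag_of <- if (!is.null(ranking)) {
    setNames(ranking$magnitude, ranking$feature)
  } else {
    setNames(rep(NA_real_, length(selected)), selected)
  }
  min_members <- ceiling(min_fraction * length(selected))

  themes <- sort(unique(unlist(theme_map)))
  rows <- lapply(themes, function(tn) {
    vars_in <- names(theme_map)[vapply(theme_map, function(t) tn %in% t,
                                       logical(1))]
    mem <- selected[var_of[selected] %in% vars_in]
    tibble::tibble(theme = tn, n_members = length(mem),
                   members = list(mem),
                   coefficient_mass = sum(abs(mag_of[mem])),
                   qualifies = length(mem) >= min_members &&
                     length(mem) > 0L)
  })
  uncat <- selected[!var_of[selected] %in% names(theme_map)]
  rows[[length(rows) + 1L]] <- tibble::tibble(
    theme = "<uncategorized>", n_members = length(uncat),
    members = list(uncat), coefficient_mass = sum(abs(mag_of[uncat])),
    qualifies = FALSE
  )
  out <- do.call(rbind, rows)
  attr(out, "min_members") <- min_members
  class(out) <- c("theme_summary", class(out))
  out
}

#' Choose the theme to drop
#'
#' Default rule (`max_coefficient`): walk the ranked selected features from
#' the top; the first feature belonging to at least one qualifying theme
#' determines the drop — if its variable belongs to several qualifying
#' themes, the one with the largest `coefficient_mass` wins. The
#' `max_variance` alternative drops the qualifying theme whose member
#' coefficients have the largest variance.
#'
#' @param summaries A `theme_summary` from [assign_themes()].
#' @param ranking The `coefficient_ranking` of the current iteration.
#' @param selected The selected features of the current iteration.
#' @param rule `"max_coefficient"` (default) or `"max_variance"`.
#' @return `NULL` when no theme qualifies (signals loop termination), else
#'   list with `theme` and `features` (the theme's selected members, to be
#'   removed from later designs).
#' @export
choose_drop_theme <- function(summaries, ranking, selected,
                              rule = c("max_coefficient", "max_variance")) {
  rule <- match.arg(rule)
  qual <- summaries[summaries$qualifies & summaries$theme != "<uncategorized>", ]
  if (nrow(qual) == 0L) return(NULL)

  if (rule == "max_variance") {
    coef_of <- setNames(ranking$coefficient, ranking$feature)
    vv <- vapply(qual$members, function(m) {
      if (length(m) < 2L) 0 else var(coef_of[m])
    }, numeric(1))
    pick <- qual[order(-vv, qual$theme)[1L], ]
    return(list(theme = pick$theme, features = pick$members[[1L]]))
  }
  ranked_selected <- ranking$feature[ranking$feature %in% selected]
  for (f in ranked_selected) {
    holds <- vapply(qual$members, function(m) f %in% m, logical(1))
    if (any(holds)) {
      cand <- qual[holds, ]
      pick <- cand[order(-cand$coefficient_mass, cand$theme)[1L], ]
      return(list(theme = pick$theme, features = pick$members[[1L]]))
    }
  }
  NULL # qualifying themes hold no ranked selected feature (uncategorized top)
}

#' Evaluate the ITA stopping rules
#'
#' Checked in order on the latest iteration record: (1) test AUC below
#' `auc_threshold`; (2) no new variables — the latest selected set adds
#' nothing to the union of all prior selected sets; (3) no new qualifying
#' themes for the last `patience` iterations; (4) `max_iterations` reached
#' (safety stop).
#'
#' @param records List of iteration records (each with `test_auc`,
#'   `selected`, `new_themes`), ordered by iteration; or an `ita_trace`.
#' @param auc_threshold Stop when the latest test AUC falls below this
#'   (default 0.65).
#' @param patience Number of consecutive theme-less iterations tolerated
#'   (default 3).
#' @param max_iterations Hard cap on iterations (default 20).
#' @return List with `stop` (logical) and `reason` (`NA` or one of
#'   `"auc_below_threshold"`, `"no_new_variables"`,
#'   `"no_new_themes_patience"`, `"max_iterations"`).
#' @export
check_stop <- function(records, auc_threshold = 0.65, patience = 3L,
                       max_iterations = 20L) {
  if (inherits(records, "ita_trace")) records <- records$iterations
  stopifnot(length(records) >= 1L)
  k <- length(records)
  latest <- records[[k]]
  if (is.finite(latest$test_auc) && latest$test_auc < auc_threshold) {
    return(list(stop = TRUE, reason = "auc_below_threshold"))
  }
  prior_union <- unique(unlist(lapply(records[seq_len(k - 1L)],
                                      function(r) r$selected)))
  if (length(setdiff(latest$selected, prior_union)) == 0L) {
    return(list(stop = TRUE, reason = "no_new_variables"))
  }
  if (k >= patience) {
    recent <- records[(k - patience + 1L):k]
    if (all(vapply(recent, function(r) length(r$new_themes) == 0L,
                   logical(1)))) {
      return(list(stop = TRUE, reason = "no_new_themes_patience"))
    }
  }
  if (k >= max_iterations) {
    return(list(stop = TRUE, reason = "max_iterations"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' ITA run configuration
#'
#' @param lambda_grid Penalty grid for both regularized stages.
#' @param cv_folds Stratified CV folds for penalty selection.
#' @param min_fraction Theme qualification threshold (fraction of selected
#'   features; default 0.05).
#' @param auc_threshold,patience,max_iterations Stopping rules; see
#'   [check_stop()].
#' @param ber_threshold Hard classification threshold for the BER.
#' @param drop_rule See [choose_drop_theme()].
#' @param smoothing_window,knee_inclusive See [knee_point()].
#' @param signed_ranking See [rank_coefficients()].
#' @param seed Integer master seed; per-iteration seeds are derived from it.
#' @return List of class `ita_config`.
#' @export
ita_config <- function(lambda_grid = lambda_grid_default(), cv_folds = 5L,
                       min_fraction = 0.05, auc_threshold = 0.65,
                       patience = 3L, max_iterations = 20L,
                       ber_threshold = 0.5,
                       drop_rule = c("max_coefficient", "max_variance"),
                       smoothing_window = 1L, knee_inclusive = FALSE,
                       signed_ranking = FALSE, seed = 1L) {
  structure(list(lambda_grid = lambda_grid, cv_folds = cv_folds,
                 min_fraction = min_fraction, auc_threshold = auc_threshold,
                 patience = patience, max_iterations = max_iterations,
                 ber_threshold = ber_threshold,
                 drop_rule = match.arg(drop_rule),
                 smoothing_window = smoothing_window,
                 knee_inclusive = knee_inclusive,
                 signed_ranking = signed_ranking, seed = as.integer(seed)),
            class = "ita_config")
}

#' Run the iterative thematic analysis loop
#'
#' @param design An [encoded_design].
#' @param labels Binary outcome labels aligned with the design rows.
#' @param split A [split_indices] from [split_train_test()].
#' @param theme_map Named list variable -> themes.
#' @param config An [ita_config].
#' @return Object of class `ita_trace`: list with `iterations` (one audit
#'   record per iteration: counts, selected features, qualifying/new
#'   themes, new variables, dropped theme/features, train/test AUC, test
#'   BER), `stop_reason`, and the `config`.
#' @export
run_ita <- function(design, labels, split, theme_map, config = ita_config()) {
  stopifnot(inherits(design, "encoded_design"),
            inherits(split, "split_indices"),
            inherits(config, "ita_config"))
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == nrow(design$matrix))
  validate_theme_map(theme_map)

  xtr_all <- design$matrix[split$train_idx, , drop = FALSE]
  xte_all <- design$matrix[split$test_idx, , drop = FALSE]
  ytr <- labels[split$train_idx]
  yte <- labels[split$test_idx]
  current <- design$feature_names
  records <- list()
  qualified_ever <- character()
  selected_union <- character()
  stop_reason <- NA_character_

  for (iter in seq_len(config$max_iterations)) {
    seed_i <- derive_seed(config$seed, iter)
    lasso <- tryCatch(
      fit_l1_logistic(xtr_all[, current, drop = FALSE], ytr,
                      lambda_grid = config$lambda_grid,
                      cv_folds = config$cv_folds, seed = seed_i),
      error = function(e) e
    )
    empty_support <- inherits(lasso, "error")
    if (!empty_support) {
      nz <- tryCatch(nonzero_features(lasso), error = function(e) NULL)
      empty_support <- is.null(nz)
    }
    if (empty_support) {
      if (iter == 1L) {
        stop("iteration-1 lasso retained no features; check the design, ",
             "labels and lambda_grid", call. = FALSE)
      }
      # an empty selection adds no new variables: record and stop
      records[[iter]] <- list(
        iteration = iter, n_features = length(current),
        n_lasso_nonzero = 0L, selected = character(),
        qualifying_themes = character(), new_themes = character(),
        new_variables = character(), dropped_theme = NA_character_,
        dropped_features = character(), lambda_l1 = NA_real_,
        lambda_l2 = NA_real_, knee_index = NA_integer_, degenerate_knee = NA,
        train_auc = NA_real_, test_auc = NA_real_, test_ber = NA_real_,
        threshold = config$ber_threshold
      )
      stop_reason <- "no_new_variables"
      break
    }

    ridge <- fit_l2_logistic(xtr_all[, nz, drop = FALSE], ytr,
                             lambda_grid = config$lambda_grid,
                             cv_folds = config$cv_folds, seed = seed_i)
    ranking <- rank_coefficients(ridge, signed = config$signed_ranking)
    if (nrow(ranking) >= 4L) {
      knee <- knee_point(ranking, smoothing_window = config$smoothing_window,
                         inclusive = config$knee_inclusive)
      selected <- knee$selected
      knee_index <- knee$knee_index
      degenerate <- knee$degenerate
    } else {
      selected <- ranking$feature # too short for curvature: keep all
      knee_index <- NA_integer_
      degenerate <- TRUE
    }
    if (length(selected) == 0L) selected <- ranking$feature[1L]

    train_scores <- predict_prob(ridge, xtr_all)
    test_scores <- predict_prob(ridge, xte_all)
    m_test <- classification_metrics(test_scores, yte, config$ber_threshold)
    train_auc <- auc(train_scores, ytr)

    summaries <- assign_themes(selected, theme_map, design$provenance,
                               ranking, config$min_fraction)
    qualifying <- summaries$theme[summaries$qualifies]
    new_themes <- setdiff(qualifying, qualified_ever)
    new_variables <- setdiff(selected, selected_union)

    records[[iter]] <- list(
      iteration = iter, n_features = length(current),
      n_lasso_nonzero = length(nz), selected = selected,
      qualifying_themes = qualifying, new_themes = new_themes,
      new_variables = new_variables, dropped_theme = NA_character_,
      dropped_features = character(), lambda_l1 = lasso$lambda,
      lambda_l2 = ridge$lambda, knee_index = knee_index,
      degenerate_knee = degenerate, train_auc = train_auc,
      test_auc = m_test$auc, test_ber = m_test$ber,
      threshold = config$ber_threshold
    )
    qualified_ever <- union(qualified_ever, qualifying)
    selected_union <- union(selected_union, selected)

    decision <- check_stop(records, config$auc_threshold, config$patience,
                           config$max_iterations)
    if (decision$stop) {
      stop_reason <- decision$reason
      break
    }
    drop <- choose_drop_theme(summaries, ranking, selected, config$drop_rule)
    if (is.null(drop)) {
      # no qualifying theme to drop: the loop cannot proceed
      stop_reason <- "no_new_themes_patience"
      break
    }
    records[[iter]]$dropped_theme <- drop$theme
    records[[iter]]$dropped_features <- drop$features
    current <- setdiff(current, drop$features)
    if (length(current) < 2L) {
      stop_reason <- "max_iterations"
      break
    }
  }
  if (is.na(stop_reason)) stop_reason <- "max_iterations"
  structure(list(iterations = records, stop_reason = stop_reason,
                 config = config),
            class = "ita_trace")
}

#' @export
print.ita_trace <- function(x, ...) {
  cat(sprintf("ITA trace: %d iteration(s), stop reason: %s\n",
              length(x$iterations), x$stop_reason))
  print(ita_report(x))
  invisible(x)
}

#' Per-iteration report table
#'
#' One row per iteration: feature counts, qualifying-theme counts, the
#' dropped theme, and train/test AUC plus test BER (the per-round metric
#' trace of the iterative models).
#'
#' @param trace An `ita_trace`.
#' @return A tibble.
#' @export
ita_report <- function(trace) {
  stopifnot(inherits(trace, "ita_trace"))
  rows <- lapply(trace$iterations, function(r) {
    tibble::tibble(
      iteration = r$iteration, n_features = r$n_features,
      n_lasso_nonzero = r$n_lasso_nonzero, n_selected = length(r$selected),
      n_qualifying = length(r$qualifying_themes),
      n_new_themes = length(r$new_themes),
      n_new_variables = length(r$new_variables),
      dropped_theme = r$dropped_theme,
      train_auc = r$train_auc, test_auc = r$test_auc, test_ber = r$test_ber
    )
  })
  do.call(rbind, rows)
}

#' Serialize an ITA trace to JSON Lines
#'
#' One iteration record per line, followed by a terminal line
#' `{"stop_reason": ...}`. The stopping reason is re-derivable from the
#' record lines alone via [check_stop()] (audit property).
#'
#' @param trace An `ita_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ita_trace"))
  lines <- vapply(trace$iterations, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  lines <- c(lines, jsonlite::toJSON(list(stop_reason = trace$stop_reason),
                                     auto_unbox = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ITA trace from JSON Lines
#'
#' @param path Path written by [write_trace()].
#' @return An `ita_trace` (without the fitted-model objects; `config` is
#'   not round-tripped).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  parsed <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  is_tail <- vapply(parsed, function(p) identical(names(p), "stop_reason"),
                    logical(1))
  records <- lapply(parsed[!is_tail], function(r) {
    for (f in c("selected", "qualifying_themes", "new_themes",
                "new_variables", "dropped_features")) {
      r[[f]] <- as.character(r[[f]] %||% character())
    }
    r$dropped_theme <- r$dropped_theme %||% NA_character_
    for (f in c("train_auc", "test_auc", "test_ber")) {
      r[[f]] <- as.numeric(r[[f]] %||% NA_real_)
    }
    r
  })
  stop_reason <- if (any(is_tail)) {
    parsed[[which(is_tail)[1L]]]$stop_reason
  } else {
    NA_character_
  }
  structure(list(iterations = records, stop_reason = stop_reason,
                 config = NULL),
            class = "ita_trace")
}
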