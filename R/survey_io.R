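# Survey table input, validation, outcome construction, encoding, splitting
# and descriptive summaries.
#
# The analytic input is a respondent-level table in which every column is
# declared (by a schema sidecar) as categorical, binary, or numeric, with a
# per-column missing-value token. Internally, missing values are normalized
# to NA; categorical cells are kept as character, binary as 0/1 integers,
# numeric as doubles.

KINDS <- c("categorical", "binary", "numeric")
BINARY_TOKENS <- c("0" = 0L, "1" = 1L, "no" = 0L, "yes" = 1L,
                   "false" = 0L, "true" = 1L)

#' Declare a survey schema
#'
#' @param columns Named list: `column -> kind` (string) or
#'   `column -> list(kind =, missing_token =)`.
#' @param default_missing_token Token standing for missing cells in columns
#'   that do not declare their own.
#' @return Tibble of class `survey_schema` with columns `column`, `kind`,
#'   `missing_token`.
#' @export
survey_schema <- function(columns, default_missing_token = ".") {
  stopifnot(is.list(columns), length(columns) >= 1L,
            !is.null(names(columns)), !anyDuplicated(names(columns)))
  rows <- lapply(names(columns), function(nm) {
    d <- columns[[nm]]
    if (is.character(d) && length(d) == 1L) d <- list(kind = d)
    kind <- match.arg(d$kind, KINDS)
    tibble::tibble(column = nm, kind = kind,
                   missing_token = d$missing_token %||% default_missing_token)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("survey_schema", class(out))
  out
}

#' Read a schema sidecar (YAML)
#'
#' Expected layout: `column: {kind: categorical|binary|numeric,
#' missing_token: "."}` (a bare string is read as the kind).
#'
#' @param path Path to the YAML file.
#' @inheritParams survey_schema
#' @return A `survey_schema`.
#' @export
read_schema <- function(path, default_missing_token = ".") {
  survey_schema(yaml::read_yaml(path), default_missing_token)
}

#' Construct a validated survey table
#'
#' @param data Data frame of raw cells (character is fine; values are
#'   validated and coerced per the schema).
#' @param schema A [survey_schema] declaring every column of `data`.
#' @return Object of class `survey_table`: list with `data` (tibble, missing
#'   normalized to `NA`), `schema`, `n_rows`.
#' @export
survey_table <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "survey_schema"))
  if (nrow(data) < 1L) stop("survey table must have at least one row")
  if (anyDuplicated(names(data))) stop("column names must be unique")
  undeclared <- setdiff(names(data), schema$column)
  if (length(undeclared) > 0L) {
    stop("schema error: undeclared column(s): ", paste(undeclared, collapse = ", "))
  }
  absent <- setdiff(schema$column, names(data))
  if (length(absent) > 0L) {
    stop("schema error: declared column(s) absent from data: ",
         paste(absent, collapse = ", "))
  }
  cols <- lapply(seq_len(nrow(schema)), function(i) {
    nm <- schema$column[i]
    parse_column(as.character(data[[nm]]), nm, schema$kind[i],
                 schema$missing_token[i])
  })
  names(cols) <- schema$column
  out <- list(data = tibble::as_tibble(cols), schema = schema,
              n_rows = nrow(data))
  class(out) <- "survey_table"
  out
}

parse_column <- function(x, name, kind, missing_token) {
  x[is.na(x) | x == missing_token] <- NA_character_
  obs <- which(!is.na(x))
  if (kind == "categorical") return(x)
  if (kind == "binary") {
    v <- BINARY_TOKENS[tolower(x[obs])]
    bad <- obs[is.na(v)]
    if (length(bad) > 0L) {
      stop(sprintf("parse error: cell '%s' at row %d of binary column '%s'",
                   x[bad[1L]], bad[1L], name))
    }
    out <- rep(NA_integer_, length(x))
    out[obs] <- unname(v)
    return(out)
  }
  # numeric
  v <- suppressWarnings(as.numeric(x[obs]))
  bad <- obs[is.na(v)]
  if (length(bad) > 0L) {
    stop(sprintf("parse error: cell '%s' at row %d of numeric column '%s'",
                 x[bad[1L]], bad[1L], name))
  }
  out <- rep(NA_real_, length(x))
  out[obs] <- v
  out
}

#' Load a survey CSV with its schema
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @param schema A [survey_schema], or a path to a YAML schema sidecar.
#' @return A validated [survey_table].
#' @export
load_survey <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  survey_table(raw, schema)
}

#' Specify how the non-marital sexual violence outcome is built
#'
#' @param violence_flag_column Binary column: has the respondent ever been
#'   forced into sexual intercourse or other sexual acts, by anyone.
#' @param perpetrator_columns Binary indicator columns, one per perpetrator
#'   type reported for that violence.
#' @param husband_codes Subset of `perpetrator_columns` counted as husband /
#'   former husband (violence by these alone is marital, not NMSV).
#' @return Object of class `outcome_spec`.
#' @export
outcome_spec <- function(violence_flag_column, perpetrator_columns,
                         husband_codes) {
  stopifnot(is.character(violence_flag_column), length(violence_flag_column) == 1L,
            is.character(perpetrator_columns), length(perpetrator_columns) >= 1L,
            is.character(husband_codes))
  if (!all(husband_codes %in% perpetrator_columns)) {
    stop("husband_codes must be a subset of perpetrator_columns")
  }
  structure(list(violence_flag_column = violence_flag_column,
                 perpetrator_columns = perpetrator_columns,
                 husband_codes = husband_codes),
            class = "outcome_spec")
}

#' Construct the NMSV outcome labels
#'
#' A respondent is labelled `1` (NMSV) iff the ever-forced-sex flag is yes
#' AND at least one non-husband perpetrator is indicated. Respondents with
#' no reported sexual violence, or whose only indicated perpetrator is a
#' (former) husband, are labelled `0`. A yes flag with no perpetrator
#' indicated at all also yields `0` (no non-husband perpetrator on record).
#' Rows with a missing violence flag are excluded from the labels and
#' reported via the `excluded_rows` attribute.
#'
#' @param table A [survey_table].
#' @param spec An [outcome_spec]; all named columns must exist in `table`.
#' @return Integer 0/1 vector, one entry per retained row, with attributes
#'   `row_index` (retained row numbers) and `excluded_rows` (rows dropped
#'   for a missing violence flag).
#' @export
construct_nmsv_outcome <- function(table, spec) {
  stopifnot(inherits(table, "survey_table"), inherits(spec, "outcome_spec"))
  need <- c(spec$violence_flag_column, spec$perpetrator_columns)
  absent <- setdiff(need, names(table$data))
  if (length(absent) > 0L) {
    stop("outcome spec column(s) absent from table: ",
         paste(absent, collapse = ", "))
  }
  flag_kind <- table$schema$kind[table$schema$column == spec$violence_flag_column]
  if (flag_kind != "binary") stop("violence flag column must be binary")

  flag <- table$data[[spec$violence_flag_column]]
  keep <- which(!is.na(flag))
  excluded <- which(is.na(flag))
  if (length(excluded) > 0L) {
    message(length(excluded), " row(s) excluded for missing violence flag")
  }
  non_husband <- setdiff(spec$perpetrator_columns, spec$husband_codes)
  perp <- as.matrix(table$data[keep, non_husband, drop = FALSE])
  perp[is.na(perp)] <- 0L # unindicated perpetrator counts as absent
  any_nonhusband <- as.integer(rowSums(perp == 1L) > 0L)
  labels <- as.integer(flag[keep] == 1L & any_nonhusband == 1L)
  if (length(unique(labels)) == 1L) {
    warning("all NMSV labels are identical; downstream models will fail")
  }
  attr(labels, "row_index") <- keep
  attr(labels, "excluded_rows") <- excluded
  labels
}

#' One-hot encode a survey table into a model design matrix
#'
#' Each categorical column with k observed levels becomes k 0/1 indicator
#' features (plus a `<missing>` indicator under the `own_category` policy if
#' any cell is missing). Binary columns pass through as a single 0/1
#' feature. Numeric columns are standardized to zero mean / unit variance on
#' observed values and median-imputed, with a companion missing indicator.
#'
#' @param table A [survey_table].
#' @param missing_policy `"own_category"` (default; keeps every row, missing
#'   becomes its own indicator) or `"drop_row"` (rows with any missing cell
#'   are dropped; see the `row_index` field to realign labels).
#' @return Object of class `encoded_design`: list with `matrix` (named
#'   columns), `feature_names`, `provenance` (tibble feature/variable/
#'   category), `constant_features` (flagged, never silently dropped),
#'   `row_index` (rows of the original table present in the matrix).
#' @export
one_hot_encode <- function(table, missing_policy = c("own_category", "drop_row")) {
  stopifnot(inherits(table, "survey_table"))
  missing_policy <- match.arg(missing_policy)
  data <- table$data
  rows <- seq_len(table$n_rows)
  if (missing_policy == "drop_row") {
    rows <- which(stats::complete.cases(data))
    if (length(rows) == 0L) stop("drop_row policy removed every row")
    data <- data[rows, , drop = FALSE]
  }
  MISSING_LABEL <- "<missing>"
  blocks <- list(); prov <- list()
  for (i in seq_len(nrow(table$schema))) {
    nm <- table$schema$column[i]
    kind <- table$schema$kind[i]
    x <- data[[nm]]
    if (kind == "categorical") {
      levels <- sort(unique(x[!is.na(x)]))
      if (length(levels) == 0L) stop("column '", nm, "' has no observed values")
      cats <- levels
      if (anyNA(x)) cats <- c(cats, MISSING_LABEL)
      xm <- ifelse(is.na(x), MISSING_LABEL, x)
      block <- vapply(cats, function(lv) as.numeric(xm == lv),
                      numeric(length(xm)))
      block <- matrix(block, ncol = length(cats))
      colnames(block) <- paste0(nm, "=", cats)
      blocks[[nm]] <- block
      prov[[nm]] <- tibble::tibble(feature = colnames(block), variable = nm,
                                   category = cats)
    } else if (kind == "binary") {
      v <- as.numeric(x)
      cols <- list()
      if (anyNA(v)) {
        miss <- as.numeric(is.na(v))
        v[is.na(v)] <- 0
        cols[[paste0(nm, "=", MISSING_LABEL)]] <- miss
      }
      block <- cbind(v, if (length(cols)) do.call(cbind, cols))
      colnames(block)[1L] <- nm
      blocks[[nm]] <- block
      prov[[nm]] <- tibble::tibble(feature = colnames(block), variable = nm,
                                   category = c("binary", rep(MISSING_LABEL,
                                                              length(cols))))
    } else {
      v <- as.numeric(x)
      obs <- !is.na(v)
      mu <- mean(v[obs]); s <- sd(v[obs])
      z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mu) / s
      z[!obs] <- median(z[obs])
      cols <- list()
      if (any(!obs)) cols[[paste0(nm, "=", MISSING_LABEL)]] <- as.numeric(!obs)
      block <- cbind(z, if (length(cols)) do.call(cbind, cols))
      colnames(block)[1L] <- nm
      blocks[[nm]] <- block
      prov[[nm]] <- tibble::tibble(feature = colnames(block), variable = nm,
                                   category = c("numeric", rep(MISSING_LABEL,
                                                               length(cols))))
    }
  }
  mat <- do.call(cbind, unname(blocks))
  provenance <- do.call(rbind, unname(prov))
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate feature names after encoding: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  }
  const <- colnames(mat)[apply(mat, 2, function(cl) length(unique(cl)) == 1L)]
  if (length(const) > 0L) {
    message(length(const), " constant feature(s) flagged (retained): ",
            paste(head(const, 5), collapse = ", "))
  }
  out <- list(matrix = mat, feature_names = colnames(mat),
              provenance = provenance, constant_features = const,
              row_index = rows)
  class(out) <- "encoded_design"
  out
}

#' Split rows into training and test sets
#'
#' Assignment is uniform at random without replacement, deterministic given
#' `seed`, and (by default) stratified by label so that a ~1%-prevalence
#' outcome cannot leave the test set without positives. The test set size is
#' exactly `round(fraction * n)` (largest-remainder allocation across
#' classes under stratification).
#'
#' @param design An [encoded_design] (or any matrix) supplying the row count.
#' @param labels Binary labels aligned with the design rows.
#' @param fraction Test fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @param stratified Set `FALSE` for plain unstratified assignment.
#' @return Object of class `split_indices`: `train_idx`, `test_idx`,
#'   `fraction`, `seed`.
#' @export
split_train_test <- function(design, labels, fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  n <- if (inherits(design, "encoded_design")) nrow(design$matrix) else nrow(design)
  labels <- as_binary_labels(labels)
  stopifnot(length(labels) == n)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  assert_both_classes(labels, "split_train_test()")
  n_test <- round(fraction * n)
  if (n_test < 1L || n_test >= n) stop("fraction leaves an empty train or test set")

  test_idx <- if (!stratified) {
    with_seed(seed, sample(n, n_test))
  } else {
    classes <- sort(unique(labels))
    exact <- vapply(classes, function(cl) fraction * sum(labels == cl), numeric(1))
    base <- floor(exact)
    rem <- n_test - sum(base)
    if (rem > 0) {
      top_up <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[top_up] <- base[top_up] + 1
    }
    with_seed(seed, {
      unlist(lapply(seq_along(classes), function(j) {
        pool <- which(labels == classes[j])
        sample(pool, base[j])
      }))
    })
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(labels[train_idx])) < 2L) {
    stop("a class is absent from the training portion; decrease fraction")
  }
  structure(list(train_idx = train_idx, test_idx = test_idx,
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_indices")
}

#' Descriptive sample summary
#'
#' Prevalence of the outcome and per-column distributions, with percentages
#' computed on non-missing denominators.
#'
#' @param table A [survey_table].
#' @param labels Binary outcome labels aligned with the table rows.
#' @return List of class `sample_summary`: `n`, `n_positive`,
#'   `prevalence_pct`, and `columns` (per categorical/binary column a tibble
#'   of level percentages; per numeric column mean and sd).
#' @export
summarize_sample <- function(table, labels) {
  stopifnot(inherits(table, "survey_table"))
  labels <- as_binary_labels(labels)
  if (length(labels) != table$n_rows) {
    stop("labels must align with the table rows")
  }
  if (table$n_rows == 0L) stop("empty table")
  cols <- list()
  for (i in seq_len(nrow(table$schema))) {
    nm <- table$schema$column[i]
    x <- table$data[[nm]]
    if (table$schema$kind[i] == "numeric") {
      cols[[nm]] <- tibble::tibble(mean = mean(x, na.rm = TRUE),
                                   sd = sd(x, na.rm = TRUE))
    } else {
      obs <- x[!is.na(x)]
      tab <- table(as.character(obs))
      cols[[nm]] <- tibble::tibble(level = names(tab),
                                   pct = derived_rate(as.numeric(tab),
                                                      length(obs)))
    }
  }
  structure(list(n = table$n_rows, n_positive = sum(labels == 1L),
                 prevalence_pct = derived_rate(sum(labels == 1L),
                                               length(labels)),
                 columns = cols),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("Sample of %d respondents; %d positive (prevalence %.2f%%)\n",
              x$n, x$n_positive, x$prevalence_pct))
  invisible(x)
}

#' Persist an encoded design
#'
#' Writes the matrix in MatrixMarket text format alongside a
#' feature-provenance TSV (`<path>.features.tsv`).
#'
#' @param design An [encoded_design].
#' @param path Output path for the MatrixMarket file.
#' @export
write_encoded_design <- function(design, path) {
  stopifnot(inherits(design, "encoded_design"))
  Matrix::writeMM(Matrix::Matrix(design$matrix, sparse = TRUE), path)
  prov <- design$provenance
  prov$constant <- prov$feature %in% design$constant_features
  write.table(prov, paste0(path, ".features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
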