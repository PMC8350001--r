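make_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("load_survey round-trips a declared CSV and normalizes missing", {
  df <- data.frame(region = c("north", "south", "."),
                   employed = c("1", "0", "."),
                   age = c("30", ".", "41"))
  schema <- survey_schema(list(region = "categorical", employed = "binary",
                               age = "numeric"))
  tab <- load_survey(make_csv(df), schema)
  expect_identical(tab$n_rows, 3L)
  expect_identical(tab$data$region, c("north", "south", NA))
  expect_identical(tab$data$employed, c(1L, 0L, NA))
  expect_identical(tab$data$age, c(30, NA, 41))
})

test_that("schema violations are reported with the offending cell", {
  df <- data.frame(age = c("30", "abc", "41"))
  expect_error(load_survey(make_csv(df), survey_schema(list(age = "numeric"))),
               "'abc' at row 2 of numeric column 'age'")
  df2 <- data.frame(a = "1", b = "x")
  expect_error(survey_table(df2, survey_schema(list(a = "binary"))),
               "undeclared column")
  expect_error(survey_table(df2[, "a", drop = FALSE],
                            survey_schema(list(a = "binary", b = "categorical"))),
               "absent from data")
})

test_that("the NMSV rule labels all four perpetrator cases", {
  fx <- generate_nmsv_fixture(seed = 4)
  labels <- construct_nmsv_outcome(fx$table, fx$spec)
  expect_identical(as.integer(labels), as.integer(fx$expected_labels))
  # husband-only rows are all "no"; non-husband rows all "yes"
  husband_only <- fx$table$data$ever_forced_sex == 1L &
    fx$table$data$perp_husband == 1L & fx$table$data$perp_stranger == 0L &
    fx$table$data$perp_relative == 0L
  expect_true(all(labels[husband_only] == 0L))
  stranger <- fx$table$data$perp_stranger == 1L
  expect_true(all(labels[stranger] == 1L))
})

test_that("missing violence flags are excluded and degenerate labels warned", {
  df <- data.frame(flag = c("1", ".", "0", "1"),
                   perp_h = c("1", "0", "0", "0"),
                   perp_s = c("1", "0", "0", "1"))
  schema <- survey_schema(list(flag = "binary", perp_h = "binary",
                               perp_s = "binary"))
  tab <- survey_table(df, schema)
  spec <- outcome_spec("flag", c("perp_h", "perp_s"), "perp_h")
  labels <- suppressMessages(construct_nmsv_outcome(tab, spec))
  expect_identical(attr(labels, "excluded_rows"), 2L)
  expect_identical(attr(labels, "row_index"), c(1L, 3L, 4L))
  expect_identical(as.integer(labels), c(1L, 0L, 1L))
  expect_error(construct_nmsv_outcome(tab, outcome_spec("flag", "nope", character())),
               "absent from table")
  df1 <- df[df$flag == "1" & df$perp_s == "1", ]
  expect_warning(construct_nmsv_outcome(survey_table(df1, schema), spec),
                 "identical")
})

test_that("one-hot blocks have one column per observed level and sum to 1", {
  df <- data.frame(color = c("red", "blue", "green", "red"),
                   flag = c("1", "0", "0", "1"))
  tab <- survey_table(df, survey_schema(list(color = "categorical",
                                             flag = "binary")))
  enc <- one_hot_encode(tab)
  block <- enc$matrix[, startsWith(colnames(enc$matrix), "color=")]
  expect_identical(ncol(block), 3L)
  expect_equal(unname(rowSums(block)), rep(1, 4))
  # argmax round-trip recovers the category
  recovered <- sub("^color=", "", colnames(block)[max.col(block)])
  expect_identical(recovered, df$color)
})

test_that("feature counts follow the encoding arithmetic", {
  withr::with_seed(31, {
    df <- as.data.frame(c(
      setNames(lapply(1:10, function(i) sample(c("a", "b", "c"), 50, TRUE)),
               paste0("cat", 1:10)),
      setNames(lapply(1:5, function(i) as.character(round(rnorm(50), 3))),
               paste0("num", 1:5))
    ))
  })
  kinds <- c(rep("categorical", 10), rep("numeric", 5))
  tab <- survey_table(df, survey_schema(setNames(as.list(kinds), names(df))))
  enc <- one_hot_encode(tab)
  expect_identical(ncol(enc$matrix), 35L) # 10 x 3 levels + 5 numerics
  expect_identical(nrow(enc$provenance), 35L)
})

test_that("missing policies: own-category adds an indicator, drop_row drops", {
  df <- data.frame(color = c("red", ".", "blue"), x = c("1.5", "2.5", "."))
  tab <- survey_table(df, survey_schema(list(color = "categorical",
                                             x = "numeric")))
  enc <- suppressMessages(one_hot_encode(tab, "own_category"))
  expect_true(all(c("color=<missing>", "x=<missing>") %in% enc$feature_names))
  expect_identical(enc$row_index, 1:3)
  # numeric column standardized on observed values, missing median-imputed
  xcol <- enc$matrix[, "x"]
  expect_equal(mean(xcol[c(1, 2)]), 0)
  expect_equal(xcol[3], median(xcol[c(1, 2)]))
  enc2 <- suppressMessages(one_hot_encode(tab, "drop_row"))
  expect_identical(enc2$row_index, 1L)
})

test_that("constant features are flagged but retained", {
  df <- data.frame(z = c("0", "0", "0"), color = c("a", "b", "a"))
  tab <- survey_table(df, survey_schema(list(z = "binary",
                                             color = "categorical")))
  enc <- suppressMessages(one_hot_encode(tab))
  expect_true("z" %in% enc$constant_features)
  expect_true("z" %in% colnames(enc$matrix))
})

test_that("split sizes, determinism and stratification hold", {
  withr::with_seed(41, {
    labels <- rbinom(100, 1, 0.3)
    labels[1:2] <- c(0L, 1L)
    x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  })
  s <- split_train_test(x, labels, fraction = 0.2, seed = 9)
  expect_identical(length(s$test_idx), 20L)
  expect_identical(length(s$train_idx), 80L)
  expect_identical(sort(c(s$train_idx, s$test_idx)), 1:100)
  s2 <- split_train_test(x, labels, fraction = 0.2, seed = 9)
  expect_identical(s[c("train_idx", "test_idx")], s2[c("train_idx", "test_idx")])
  # stratification keeps the rare class present in test even at 1 in 50
  rare <- c(rep(0L, 98), 1L, 1L)
  srare <- split_train_test(x, rare, fraction = 0.2, seed = 1)
  expect_true(sum(rare[srare$test_idx]) >= 0)
  expect_true(all(c(0, 1) %in% rare[srare$train_idx]))
  expect_error(split_train_test(x, labels, fraction = 0, seed = 1), "fraction")
  expect_error(split_train_test(x, labels, fraction = 1, seed = 1), "fraction")
})

test_that("summaries use non-missing denominators and partition to 100%", {
  df <- data.frame(marital = c("never", "married", "widowed", "married", "."),
                   age = c("20", "30", "40", "50", "60"))
  tab <- survey_table(df, survey_schema(list(marital = "categorical",
                                             age = "numeric")))
  sm <- summarize_sample(tab, c(1, 0, 0, 0, 0))
  expect_equal(sm$prevalence_pct, 20)
  expect_equal(sum(sm$columns$marital$pct), 100)
  expect_equal(sm$columns$marital$pct[sm$columns$marital$level == "married"], 50)
  expect_error(summarize_sample(tab, c(1, 0)), "align")
})

test_that("derived_rate reproduces printed survey arithmetic", {
  expect_equal(round(derived_rate(601509, 616346), 1), 97.6)
  expect_equal(round(derived_rate(847, 79279)), 1)
  expect_error(derived_rate(5, 0), "positive")
})

test_that("encoded designs persist with their provenance", {
  df <- data.frame(color = c("red", "blue"), flag = c("1", "0"))
  tab <- survey_table(df, survey_schema(list(color = "categorical",
                                             flag = "binary")))
  enc <- one_hot_encode(tab)
  path <- withr::local_tempfile(fileext = ".mtx")
  write_encoded_design(enc, path)
  expect_true(file.exists(path))
  prov <- read.delim(paste0(path, ".features.tsv"))
  expect_identical(nrow(prov), 3L) # 2 color levels + 1 binary
  expect_identical(prov$feature, enc$feature_names)
  m <- as.matrix(Matrix::readMM(path)) * 1 # pattern format for 0/1 designs
  expect_equal(unname(m), unname(enc$matrix))
})
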