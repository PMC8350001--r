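toy_provenance <- function(vars, per_var = 1L) {
  feats <- unlist(lapply(vars, function(v) paste0(v, "=", seq_len(per_var))))
  tibble::tibble(feature = feats,
                 variable = rep(vars, each = per_var),
                 category = "x")
}

test_that("theme maps round-trip through YAML and TSV", {
  tm <- list(v1 = "violence", v2 = c("violence", "geography"), v3 = "health")
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(tm, ypath)
  expect_identical(read_theme_map(ypath), tm)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variable\tthemes", "v1\tviolence",
               "v2\tviolence, geography", "v3\thealth"), tpath)
  expect_identical(read_theme_map(tpath), tm)
  expect_error(validate_theme_map <- read_theme_map(
    { p <- withr::local_tempfile(fileext = ".yaml"); yaml::write_yaml(list(), p); p }),
    "non-empty")
})

test_that("theme-map agreement mirrors an inter-coder reliability check", {
  a <- list(v1 = "violence", v2 = "geography", v3 = "health")
  b <- list(v1 = "violence", v2 = "wealth", v3 = "health")
  expect_equal(theme_map_agreement(a, b), 100 * 2 / 3)
  expect_equal(theme_map_agreement(a, a), 100)
  # order inside a theme set does not matter
  expect_equal(theme_map_agreement(list(v = c("a", "b")),
                                   list(v = c("b", "a"))), 100)
})

test_that("theme qualification follows the 5% ceiling rule", {
  # 40 selected features from 40 variables; theme A holds 2, theme B holds 1
  vars <- sprintf("v%02d", 1:40)
  prov <- toy_provenance(vars)
  tm <- c(setNames(as.list(rep("other", 37)), vars[4:40]),
          list(v01 = "A", v02 = "A", v03 = "B"))
  selected <- prov$feature
  s <- assign_themes(selected, tm, prov, min_fraction = 0.05)
  expect_identical(attr(s, "min_members"), 2)
  expect_true(s$qualifies[s$theme == "A"])    # 2 >= ceil(0.05*40) = 2
  expect_false(s$qualifies[s$theme == "B"])   # 1 < 2
  expect_true(s$qualifies[s$theme == "other"])
})

test_that("a multi-theme variable counts in every theme it maps to", {
  prov <- toy_provenance(c("v1", "v2", "v3", "v4"))
  tm <- list(v1 = c("A", "B"), v2 = "A", v3 = "B", v4 = "C")
  s <- assign_themes(prov$feature, tm, prov, min_fraction = 0.05)
  expect_identical(s$n_members[s$theme == "A"], 2L)
  expect_identical(s$n_members[s$theme == "B"], 2L)
  expect_identical(s$n_members[s$theme == "C"], 1L)
})

test_that("unmapped variables land in a reported uncategorized bucket", {
  prov <- toy_provenance(c("v1", "v2"))
  s <- assign_themes(prov$feature, list(v1 = "A"), prov)
  un <- s[s$theme == "<uncategorized>", ]
  expect_identical(un$n_members, 1L)
  expect_false(un$qualifies)
  expect_error(assign_themes(prov$feature, list(), prov), "non-empty")
})

test_that("qualification threshold scales with the selection size", {
  vars <- sprintf("v%02d", 1:40)
  prov <- toy_provenance(vars, per_var = 2L) # doubled design
  tm <- setNames(as.list(rep("T", 40)), vars)
  s40 <- assign_themes(prov$feature[1:40], tm, prov)
  s80 <- assign_themes(prov$feature, tm, prov)
  expect_identical(attr(s80, "min_members"), 2 * attr(s40, "min_members"))
})

test_that("the drop rule follows the top-ranked feature and mass tie-break", {
  prov <- toy_provenance(c("v1", "v2", "v3", "v4", "v5"))
  ranking <- rank_coefficients(setNames(c(0.9, 0.8, 0.5, 0.3, 0.1),
                                        prov$feature))
  selected <- prov$feature
  # top feature v1 in exactly one qualifying theme
  tm1 <- list(v1 = "A", v2 = "A", v3 = "B", v4 = "B", v5 = "B")
  s1 <- assign_themes(selected, tm1, prov, ranking, min_fraction = 0.2)
  d1 <- choose_drop_theme(s1, ranking, selected)
  expect_identical(d1$theme, "A")
  expect_setequal(d1$features, prov$feature[1:2])
  # top feature in two qualifying themes: larger coefficient mass wins
  tm2 <- list(v1 = c("A", "B"), v2 = "A", v3 = "A", v4 = "B", v5 = "B")
  s2 <- assign_themes(selected, tm2, prov, ranking, min_fraction = 0.2)
  mass <- setNames(s2$coefficient_mass, s2$theme)
  d2 <- choose_drop_theme(s2, ranking, selected)
  expect_identical(d2$theme, names(which.max(mass[c("A", "B")])))
  # a single qualifying theme is forced
  tm3 <- list(v1 = "Z", v2 = "Z", v3 = "Z", v4 = "Z", v5 = "Z")
  s3 <- assign_themes(selected, tm3, prov, ranking, min_fraction = 0.2)
  expect_identical(choose_drop_theme(s3, ranking, selected)$theme, "Z")
  # no qualifying theme signals termination
  s_none <- s1
  s_none$qualifies <- FALSE
  expect_null(choose_drop_theme(s_none, ranking, selected))
})

test_that("the max-variance drop rule picks the most dispersed theme", {
  prov <- toy_provenance(c("v1", "v2", "v3", "v4"))
  ranking <- rank_coefficients(setNames(c(0.9, -0.85, 0.5, 0.48),
                                        prov$feature))
  tm <- list(v1 = "A", v2 = "A", v3 = "B", v4 = "B")
  s <- assign_themes(prov$feature, tm, prov, ranking, min_fraction = 0.2)
  d <- choose_drop_theme(s, ranking, prov$feature, rule = "max_variance")
  expect_identical(d$theme, "A") # coefficients 0.9 / -0.85 vary most
})

test_that("stopping rules fire in the declared order", {
  rec <- function(iter, auc, selected, new_themes) {
    list(iteration = iter, test_auc = auc, selected = selected,
         new_themes = new_themes)
  }
  # latest AUC below threshold
  r <- list(rec(1, 0.80, c("a", "b"), "T1"), rec(2, 0.60, c("c"), character()))
  expect_identical(check_stop(r)$reason, "auc_below_threshold")
  # nothing new in the latest selection
  r <- list(rec(1, 0.80, c("a", "b"), "T1"), rec(2, 0.75, c("b"), character()))
  expect_identical(check_stop(r)$reason, "no_new_variables")
  # three consecutive iterations without a new qualifying theme
  r <- list(rec(1, 0.8, "a", "T1"), rec(2, 0.78, "b", character()),
            rec(3, 0.77, "c", character()), rec(4, 0.76, "d", character()))
  expect_identical(check_stop(r)$reason, "no_new_themes_patience")
  # continue otherwise
  r <- list(rec(1, 0.8, "a", "T1"), rec(2, 0.78, "b", "T2"))
  expect_false(check_stop(r)$stop)
  # max iterations as the safety stop
  expect_identical(check_stop(r, max_iterations = 2)$reason, "max_iterations")
  # AUC precedence over the other rules
  r <- list(rec(1, 0.8, "a", "T1"), rec(2, 0.60, "a", character()))
  expect_identical(check_stop(r)$reason, "auc_below_threshold")
})

test_that("the ITA loop recovers planted themes on a small scenario", {
  sc <- small_scenario()
  trace <- small_trace()
  expect_s3_class(trace, "ita_trace")
  expect_true(trace$stop_reason %in% c("no_new_themes_patience",
                                       "no_new_variables",
                                       "auc_below_threshold",
                                       "max_iterations"))
  qual <- unique(unlist(lapply(trace$iterations,
                               function(r) r$qualifying_themes)))
  expect_true(all(c("t1", "t2") %in% qual))
})

test_that("dropped features leave the design and never reappear", {
  sc <- small_scenario()
  trace <- small_trace()
  records <- trace$iterations
  dropped <- lapply(records, function(r) r$dropped_features)
  # dropped sets are disjoint across iterations
  expect_identical(anyDuplicated(unlist(dropped)), 0L)
  for (k in seq_along(records)[-1]) {
    prior_dropped <- unlist(dropped[seq_len(k - 1)])
    expect_length(intersect(records[[k]]$selected, prior_dropped), 0)
    expect_identical(records[[k]]$n_features,
                     records[[k - 1]]$n_features -
                       length(records[[k - 1]]$dropped_features))
  }
})

test_that("identical config and seed give a byte-identical trace", {
  sc <- small_scenario()
  t1 <- run_ita(sc$design, sc$gen$truth$labels, sc$split, sc$gen$theme_map,
                ita_config(seed = 3))
  t2 <- run_ita(sc$design, sc$gen$truth$labels, sc$split, sc$gen$theme_map,
                ita_config(seed = 3))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trace(t1, f1); write_trace(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the stop reason is re-derivable from the serialized trace", {
  sc <- small_scenario()
  trace <- small_trace()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trace(trace, path)
  back <- read_trace(path)
  expect_identical(back$stop_reason, trace$stop_reason)
  cfg <- trace$config
  rederived <- check_stop(back$iterations, cfg$auc_threshold, cfg$patience,
                          cfg$max_iterations)
  expect_true(rederived$stop)
  expect_identical(rederived$reason, trace$stop_reason)
})

test_that("a single all-absorbing theme collapses the loop within 2 iterations", {
  # all the signal sits in one passthrough feature and the theme map sends
  # every variable to one theme: iteration 1 selects and drops the
  # informative feature, leaving pure noise for iteration 2
  df <- withr::with_seed(13, {
    signal <- rnorm(1500)
    cols <- c(list(signal = signal),
              setNames(lapply(1:8, function(i) rnorm(1500)),
                       paste0("noise", 1:8)))
    list(data = as.data.frame(lapply(cols, function(v) as.character(round(v, 6)))),
         labels = rbinom(1500, 1, plogis(2.5 * signal)))
  })
  schema <- survey_schema(setNames(as.list(rep("numeric", 9)),
                                   names(df$data)))
  design <- one_hot_encode(survey_table(df$data, schema))
  split <- split_train_test(design, df$labels, 0.2, seed = 13)
  one_theme <- setNames(as.list(rep("all", 9)), names(df$data))
  trace <- run_ita(design, df$labels, split, one_theme, ita_config(seed = 13))
  expect_true("signal" %in% trace$iterations[[1]]$selected)
  expect_lte(length(trace$iterations), 2L)
})

test_that("the report table mirrors the per-iteration metric trace", {
  sc <- small_scenario()
  trace <- small_trace()
  rep <- ita_report(trace)
  expect_identical(nrow(rep), length(trace$iterations))
  expect_true(all(rep$test_auc >= 0 & rep$test_auc <= 1, na.rm = TRUE))
  expect_true(all(rep$test_ber >= 0 & rep$test_ber <= 1, na.rm = TRUE))
  expect_identical(rep$iteration, seq_len(nrow(rep)))
})
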