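# Fixtures built in code, plus a per-session cache for the heavy
# end-to-end scenario so several test files can share one run.

# Small labelled design for model tests: `p_signal` features carry signal,
# the rest are pure noise.
make_design <- function(n, p_noise, p_signal = 0, beta = 1.5, seed = 1) {
  withr::with_seed(seed, {
    p <- p_noise + p_signal
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    eta <- if (p_signal > 0) {
      drop(x[, seq_len(p_signal), drop = FALSE] %*% rep(beta, p_signal))
    } else {
      rep(0, n)
    }
    y <- rbinom(n, 1, plogis(eta))
    list(x = x, y = y)
  })
}

# A small but realistic synthetic survey scenario (fast ITA runs).
.small_cache <- new.env(parent = emptyenv())

small_scenario <- function(seed = 3) {
  key <- paste0("sc", seed)
  if (!is.null(.small_cache[[key]])) return(.small_cache[[key]])
  themes <- tibble::tibble(name = paste0("t", 1:4), n_variables = 4L,
                           n_categories = 3L, rho = 0.6)
  cfg <- synthetic_config(n_rows = 2000L, themes = themes,
                          informative_effects = c(t1 = 1.2, t2 = 1.2),
                          target_prevalence = 0.1, seed = seed)
  gen <- generate_wide_survey(cfg)
  design <- suppressMessages(one_hot_encode(gen$table))
  split <- split_train_test(design, gen$truth$labels, 0.2, seed = seed)
  .small_cache[[key]] <- list(gen = gen, design = design, split = split,
                              cfg = cfg)
  .small_cache[[key]]
}

# One shared ITA trace on the small scenario.
small_trace <- function(seed = 3) {
  key <- paste0("tr", seed)
  if (is.null(.small_cache[[key]])) {
    sc <- small_scenario(seed)
    .small_cache[[key]] <- run_ita(sc$design, sc$gen$truth$labels, sc$split,
                                   sc$gen$theme_map, ita_config(seed = seed))
  }
  .small_cache[[key]]
}

# Cache for the reference scenario S1 (computed once per test session).
.s1_cache <- new.env(parent = emptyenv())

s1_run <- function() {
  if (!is.null(.s1_cache$res)) return(.s1_cache$res)
  gen <- generate_wide_survey(synthetic_config_s1())
  design <- suppressMessages(one_hot_encode(gen$table))
  split <- split_train_test(design, gen$truth$labels, 0.2, seed = 11)
  trace <- run_ita(design, gen$truth$labels, split, gen$theme_map,
                   ita_config(seed = 11))
  .s1_cache$res <- list(gen = gen, design = design, split = split,
                        trace = trace)
  .s1_cache$res
}

s1_nn <- function() {
  if (!is.null(.s1_cache$nn)) return(.s1_cache$nn)
  s1 <- s1_run()
  .s1_cache$nn <- nn_pipeline(s1$design, s1$gen$truth$labels, s1$split,
                              nn_config(seed = 11), seed = 11)
  .s1_cache$nn
}

# Selected source variables over a whole trace, via provenance.
trace_selected_variables <- function(trace, design) {
  feats <- unique(unlist(lapply(trace$iterations, function(r) r$selected)))
  var_of <- setNames(design$provenance$variable, design$provenance$feature)
  unique(unname(var_of[feats]))
}
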