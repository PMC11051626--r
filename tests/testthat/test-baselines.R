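test_that("mixed models consume the identical feature table as the booster", {
  st <- fixture_effects_study()
  ft <- build_features(st, feature_spec("miss_hit"))
  df <- streamgbm:::.as_model_frame(ft)
  # same rows, and every booster feature present by name
  expect_equal(nrow(df), nrow(ft$x))
  expect_true(all(colnames(ft$x) %in% names(df)))
  # categorical codes decode back to their original labels
  tr <- st$trials[st$trials$outcome %in% c("hit", "miss"), ]
  expect_equal(as.character(df$talker), tr$talker)
  expect_equal(as.character(df$ferret_id), tr$ferret_id)
})

test_that("the GLMM recovers an injected talker miss effect", {
  # shared F0 sets across talkers so the talker effect is identifiable
  cfg <- session_config(n_trials = 3500, vocab_size = 12,
                        talker_f0 = list(male = c(109, 124, 144),
                                         female = c(109, 124, 144)))
  st <- generate_study(cfg, observer_params(miss_talker_effect = 1),
                       seed = 301)
  ft <- build_features(st, feature_spec("miss_hit"))
  bl <- fit_glmm_outcome(ft, seed = 2)
  co <- bl$coefficients[bl$coefficients$term == "talkerfemale", ]
  # reference is male: the female coefficient is -1 within its 95% CI
  expect_lt(co$estimate + 1.96 * co$se, 0)
  expect_true(co$estimate - 1.96 * co$se <= -1 &
              -1 <= co$estimate + 1.96 * co$se)
  expect_equal(unname(bl$references["talker"]), "male")
  expect_equal(nrow(bl$metrics), 5)
})

test_that("an RT precursor-mismatch effect appears with the right sign", {
  st <- fixture_effects_study()
  ft <- build_features(st, feature_spec("reaction_time"))
  bl <- fit_glmm_outcome(ft, family = "gaussian", seed = 2)
  co <- bl$coefficients[bl$coefficients$term == "precursor_matchTRUE", ]
  # matched-precursor trials are faster: negative, significant coefficient
  expect_lt(co$estimate, 0)
  expect_lt(co$p_value, 0.05)
  expect_equal(co$estimate, -0.08, tolerance = 0.5)
})

test_that("zero-effect generators yield mostly non-significant effects", {
  cfg <- session_config(n_trials = 1200, vocab_size = 10,
                        talker_f0 = list(male = c(109, 124, 144),
                                         female = c(109, 124, 144)))
  n_sig <- 0; n_tests <- 0
  for (s in 1:6) {
    st <- generate_study(cfg, observer_params(), seed = 400 + s)
    ft <- build_features(st, feature_spec("reaction_time"))
    bl <- fit_glmm_outcome(ft, family = "gaussian", seed = s)
    co <- bl$coefficients[bl$coefficients$term %in%
                            c("talkerfemale", "precursor_matchTRUE",
                              "sideright"), ]
    n_sig <- n_sig + sum(co$p_value < 0.05)
    n_tests <- n_tests + nrow(co)
  }
  # at alpha = 0.05, expect ~5% false positives across 18 tests
  expect_lte(n_sig, qbinom(0.995, n_tests, 0.05))
})

test_that("OLS on the word matrix solves the exact linear case", {
  st <- fixture_null_study()
  wft <- build_word_timing_matrix(st)
  # construct a noiseless linear rule: release = target onset + 0.4
  keep <- !is.na(wft$x[, "word_0"])
  wft$x <- wft$x[keep, , drop = FALSE]
  wft$y <- wft$x[, "word_0"] + 0.4
  wft$groups <- wft$groups[keep]; wft$trial_id <- wft$trial_id[keep]
  suppressWarnings(ols <- fit_ols_response_time(wft, seed = 1))
  co <- ols$coefficients
  expect_equal(co$estimate[co$term == "word_0"], 1, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.4, tolerance = 1e-6)
  expect_lt(ols$means$test_mse, 1e-10)
})

test_that("all-sentinel columns are dropped with a warning", {
  st <- fixture_null_study()
  wft <- build_word_timing_matrix(st)
  wft$x[, "word_3"] <- NA_real_
  expect_warning(fit_ols_response_time(wft, seed = 1),
                 "all-sentinel.*word_3")
})

test_that("the booster beats OLS on a nonlinear release rule", {
  # release at the first occurrence of a confusable token: a rule linear
  # models cannot express over onset columns with absence imputation
  cfg <- session_config(n_trials = 1800, vocab_size = 12)
  obs <- observer_params(word_confusability = c(`3` = 3, `7` = 3))
  st <- generate_study(cfg, obs, seed = 302)
  wft <- build_word_timing_matrix(st)
  prot <- train_protocol("regression", max_epochs = 120,
                         early_stopping_rounds = 20, seed = 3)
  gbm <- crossval_fit(wft, prot)
  suppressWarnings(ols <- fit_ols_response_time(wft, fold = gbm$fold,
                                                seed = 3))
  expect_lt(gbm$means$test_mse, ols$means$test_mse)
})

test_that("OLS matches the booster on purely linear data", {
  set.seed(12)
  n <- 800
  x <- cbind(word_0 = runif(n, 0.5, 6.5), word_1 = runif(n, 0, 6))
  y <- x[, "word_0"] + 0.3 * x[, "word_1"] + rnorm(n, 0, 0.1)
  ft <- structure(list(x = x, y = y, groups = NULL, trial_id = 1:n,
                       meta = list(), spec = feature_spec("response_time")),
                  class = "feature_table")
  prot <- train_protocol("regression", max_epochs = 150,
                         early_stopping_rounds = 20, seed = 4)
  gbm <- crossval_fit(ft, prot)
  ols <- fit_ols_response_time(ft, fold = gbm$fold, seed = 4)
  # no false superiority: OLS is at least as good on its home turf
  expect_lte(ols$means$test_mse, gbm$means$test_mse + 0.01)
})
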