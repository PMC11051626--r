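test_that("permutation importance isolates informative features", {
  set.seed(10)
  n <- 2000
  x <- cbind(signal = rbinom(n, 1, 0.5), noise = rnorm(n))
  # the model is an exact copy of the signal feature
  pred <- function(xx) xx[, "signal"]
  y <- x[, "signal"]
  pi <- permutation_importance(pred, x = x, y = y, metric = "accuracy",
                               n_repeats = 10, seed = 2)
  expect_equal(attr(pi, "baseline"), 1)
  # label = copy of a single feature: importance ~ baseline - chance
  imp_sig <- pi$importance[pi$feature == "signal"]
  expect_equal(imp_sig, 0.5, tolerance = 0.05)
  # a feature independent of the label stays within noise
  imp_noise <- pi$importance[pi$feature == "noise"]
  sd_noise <- pi$sd[pi$feature == "noise"]
  expect_lt(abs(imp_noise), 2 * sd_noise + 1e-8)
})

test_that("gain curve ranks and the elbow rule selects features", {
  set.seed(3)
  n <- 600
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- x[, "a"] + rnorm(n, 0, 0.05)
  m <- xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                        nthread = 1, seed = 1,
                                        max_depth = 3, eta = 0.3),
                          data = xgboost::xgb.DMatrix(x, label = y),
                          nrounds = 30, verbose = 0)
  cg <- cumulative_gain_curve(m)
  expect_equal(cg$feature[1], "a")
  expect_gt(cg$cumulative[1], 0.95)
  expect_equal(cg$cumulative[nrow(cg)], 1, tolerance = 1e-6)
  expect_equal(elbow_select(cg, 1), cg$feature)
  expect_equal(elbow_select(cg, 0.9), "a")
  # two equally informative independent features split the gain evenly
  y2 <- x[, "a"] + x[, "b"] + rnorm(n, 0, 0.05)
  m2 <- xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                         nthread = 1, seed = 1,
                                         max_depth = 3, eta = 0.3),
                           data = xgboost::xgb.DMatrix(x, label = y2),
                           nrounds = 30, verbose = 0)
  cg2 <- cumulative_gain_curve(m2)
  expect_equal(cg2$gain[cg2$feature == "a"], 0.5, tolerance = 0.1)
  expect_equal(cg2$gain[cg2$feature == "b"], 0.5, tolerance = 0.1)
})

test_that("SHAP values satisfy local accuracy and the dummy axiom", {
  rep1 <- fixture_miss_report()
  sh <- shap_attribution(rep1)
  # local accuracy: contributions + expectation reproduce the raw output
  err <- abs(rowSums(sh$values) + sh$expected_value - sh$margin)
  expect_lt(max(err), 1e-10)
  expect_equal(sh$units, "log-odds")
  # double-precision margins agree with the booster's own float32 output
  pm <- predict_margin(rep1, rep1$x)
  px <- predict(rep1$model, rep1$x, outputmargin = TRUE)
  expect_lt(max(abs(pm - px)), 1e-4)
  # a feature never used by the model gets exactly zero
  used <- unique(cumulative_gain_curve(rep1)$feature)
  unused <- setdiff(colnames(sh$values), used)
  if (length(unused))
    expect_true(all(sh$values[, unused] == 0))
})

test_that("a depth-1 model attributes only the split feature", {
  set.seed(4)
  n <- 300
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.numeric(x[, "a"] > 0)
  m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                        nthread = 1, seed = 1,
                                        max_depth = 1, eta = 0.5),
                          data = xgboost::xgb.DMatrix(x, label = y),
                          nrounds = 1, verbose = 0)
  sh <- shap_attribution(m, x)
  expect_true(all(sh$values[, "b"] == 0))
  expect_equal(sh$values[, "a"], sh$margin - sh$expected_value)
})

test_that("the brute-force oracle matches the production attribution", {
  set.seed(20)
  for (s in 1:10) {
    set.seed(s)
    M <- sample(2:4, 1); n <- 60
    x <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, paste0("f", 1:M)))
    y <- rbinom(n, 1, plogis(x[, 1]))
    m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          nthread = 1, seed = s,
                                          max_depth = 3, eta = 0.3),
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = 3, verbose = 0)
    sh <- shap_attribution(m, x[1:2, , drop = FALSE])
    for (i in 1:2) {
      bf <- brute_force_shapley(m, x[i, ])
      expect_lt(max(abs(bf$phi - sh$values[i, ])), 1e-10)
      expect_lt(abs(bf$expected_value - sh$expected_value), 1e-10)
    }
  }
  # symmetry axiom: duplicated feature values with identical structure
  expect_error(brute_force_shapley(fixture_miss_report(),
                                   fixture_miss_report()$x[1, ],
                                   max_features = 4),
               "feasibility")
})

test_that("attribution grows monotonically with the injected effect", {
  set.seed(5)
  n <- 1500
  imp <- numeric(3); shp <- numeric(3)
  for (k in 1:3) {
    b <- c(0.05, 0.15, 0.45)[k]
    x <- cbind(eff = rbinom(n, 1, 0.5), covar = rnorm(n))
    y <- b * x[, "eff"] + 0.2 * x[, "covar"] + rnorm(n, 0, 0.2)
    ft <- structure(list(x = x, y = y, groups = NULL, trial_id = 1:n,
                         meta = list(), spec = feature_spec("reaction_time")),
                    class = "feature_table")
    r <- crossval_fit(ft, train_protocol("regression", max_epochs = 60,
                                         early_stopping_rounds = 10,
                                         n_folds = 3, seed = k))
    pi <- permutation_importance(r, n_repeats = 5, seed = 1)
    imp[k] <- pi$importance[pi$feature == "eff"]
    sh <- shap_attribution(r)
    shp[k] <- mean(abs(sh$values[, "eff"]))
  }
  expect_true(all(diff(imp) > 0))
  expect_true(all(diff(shp) > 0))
})

test_that("duplicating a feature halves permutation importance, conserves SHAP", {
  set.seed(6)
  n <- 1500
  z <- rnorm(n)
  y <- z + rnorm(n, 0, 0.2)
  fit <- function(x) {
    ft <- structure(list(x = x, y = y, groups = NULL,
                         trial_id = seq_len(n), meta = list(),
                         spec = feature_spec("reaction_time")),
                    class = "feature_table")
    # subsample columns per tree so exact duplicates both get used
    # (greedy splitting otherwise always picks the first copy)
    crossval_fit(ft, train_protocol("regression", max_epochs = 60,
                                    early_stopping_rounds = 10,
                                    n_folds = 3, seed = 2,
                                    params = list(max_depth = 3, eta = 0.1,
                                                  colsample_bytree = 0.5)))
  }
  r1 <- fit(cbind(z1 = z, noise = rnorm(n)))
  r2 <- fit(cbind(z1 = z, z2 = z, noise = rnorm(n)))
  p1 <- permutation_importance(r1, n_repeats = 5, seed = 1)
  p2 <- permutation_importance(r2, n_repeats = 5, seed = 1)
  i1 <- p1$importance[p1$feature == "z1"]
  i2 <- p2$importance[p2$feature %in% c("z1", "z2")]
  # each copy individually matters much less (the other stands in for it)
  expect_lt(max(i2), 0.6 * i1)
  # but their total SHAP attribution is conserved
  s1 <- shap_attribution(r1); s2 <- shap_attribution(r2)
  tot1 <- mean(abs(s1$values[, "z1"]))
  tot2 <- mean(abs(s2$values[, "z1"] + s2$values[, "z2"]))
  expect_equal(tot2, tot1, tolerance = 0.1)
})

test_that("dependence data decodes levels, filters groups, recovers effects", {
  # shared F0 sets keep the talker effect identifiable (talker-specific F0
  # triplets would otherwise split SHAP credit with the target-F0 feature)
  st <- generate_study(session_config(n_trials = 2500, vocab_size = 12,
                                      talker_f0 = list(male = c(109, 124, 144),
                                                       female = c(109, 124, 144))),
                       observer_params(rt_talker_effect = 0.15), seed = 77)
  ft <- build_features(st, feature_spec("reaction_time"))
  r <- crossval_fit(ft, train_protocol("regression", max_epochs = 120,
                                       early_stopping_rounds = 20, seed = 3))
  sh <- shap_attribution(r)
  dd <- dependence_data(sh, ft, "talker", color_feature = "target_f0")
  expect_setequal(unique(dd$feature_value), c("male", "female"))
  expect_true("color_value" %in% names(dd))
  # the SHAP contrast recovers the injected +0.15 s male-talker effect
  contrast <- mean(dd$shap_value[dd$feature_value == "male"]) -
    mean(dd$shap_value[dd$feature_value == "female"])
  expect_lt(abs(contrast - 0.15), 0.2 * 0.15)
  # group filter keeps only the requested ferret
  one <- dependence_data(sh, ft, "talker", groups = "F01")
  expect_true(all(one$group == "F01"))
  expect_error(dependence_data(sh, ft, "nonexistent"), "schema error")
})
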