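# shared small fixtures, built once per test run

# fast protocols for test-sized data
test_protocol_cls <- function(seed = 1)
  train_protocol("binary", max_epochs = 200, early_stopping_rounds = 25,
                 seed = seed)
test_protocol_reg <- function(seed = 1)
  train_protocol("regression", max_epochs = 150, early_stopping_rounds = 25,
                 seed = seed)

# a small study with every injectable effect switched on
fixture_effects_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- session_config(n_trials = 2500, vocab_size = 20)
      obs <- observer_params(miss_talker_effect = 1,
                             intra_rove_fa_offset = 0.5,
                             rt_precursor_mismatch_effect = 0.08,
                             word_confusability = c(`3` = 2.5, `7` = 2.5))
      cache <<- generate_study(cfg, obs, seed = 101)
    }
    cache
  }
})

# a null study: default observer, no injected effects
fixture_null_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(session_config(n_trials = 1500, vocab_size = 20),
                               observer_params(), seed = 202)
    }
    cache
  }
})

# a tiny fitted classifier on the effects study (miss/hit, balanced)
fixture_miss_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- fixture_effects_study()
      ft <- build_features(st, feature_spec("miss_hit"))
      idx <- subsample_balance(ft$y, seed = 3)
      ft$x <- ft$x[idx, , drop = FALSE]
      ft$y <- ft$y[idx]
      ft$groups <- ft$groups[idx]
      ft$trial_id <- ft$trial_id[idx]
      cache <<- crossval_fit(ft, test_protocol_cls(seed = 7))
    }
    cache
  }
})
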