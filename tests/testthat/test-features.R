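test_that("feature tables filter rows and pick labels per model", {
  st <- fixture_effects_study()
  mh <- build_features(st, feature_spec("miss_hit"))
  # target trials only, label = miss
  expect_equal(nrow(mh$x), sum(st$trials$outcome %in% c("hit", "miss")))
  expect_setequal(unique(mh$y), c(0, 1))
  expect_true(all(c("talker", "target_f0", "precursor_match") %in%
                  colnames(mh$x)))

  fa <- build_features(st, feature_spec("false_alarm"))
  expect_equal(nrow(fa$x), nrow(st$trials))
  expect_equal(sum(fa$y), sum(st$trials$outcome == "false_alarm"))

  rt <- build_features(st, feature_spec("reaction_time"))
  expect_equal(nrow(rt$x), sum(st$trials$outcome == "hit"))
  expect_true(all(rt$y > 0 & rt$y <= 2))
})

test_that("the false-alarm trial F0 is the last non-target F0 on intra roves", {
  st <- fixture_effects_study()
  fa <- build_features(st, feature_spec("false_alarm"))
  meta <- fa$meta[[match("trial_f0", vapply(fa$meta, `[[`, "", "feature"))]]
  decoded <- as.numeric(meta$levels)[fa$x[, "trial_f0"] + 1]
  intra <- st$trials$rove_mode == "intra"
  expect_equal(decoded[intra], st$trials$last_nontarget_f0[intra])
  expect_equal(decoded[!intra], st$trials$stream_f0[!intra])
})

test_that("precursor-match flag compares the preceding token's F0", {
  st <- fixture_effects_study()
  mh <- build_features(st, feature_spec("miss_hit"))
  tr <- st$trials[st$trials$outcome %in% c("hit", "miss"), ]
  manual <- is.na(tr$precursor_f0) | tr$precursor_f0 == tr$target_f0
  expect_equal(mh$x[, "precursor_match"], as.numeric(manual))
  # control trials always match
  expect_true(all(mh$x[tr$rove_mode == "control", "precursor_match"] == 1))
})

test_that("balancing subsampling follows the min-count rule", {
  key <- c(rep("hit", 90), rep("miss", 10))
  idx <- subsample_balance(key, seed = 1)
  expect_length(idx, 20)
  expect_equal(as.integer(table(key[idx])), c(10L, 10L))
  # already balanced: everything retained, order stable
  key2 <- rep(c("a", "b"), each = 50)
  expect_equal(subsample_balance(key2), 1:100)
  # three levels 400/100/150 -> 100 each
  key3 <- rep(c("x", "y", "z"), c(400, 100, 150))
  idx3 <- subsample_balance(key3, seed = 2)
  expect_equal(as.integer(table(key3[idx3])), c(100L, 100L, 100L))
  # subset of input indices only, no fabricated rows
  expect_true(all(idx3 %in% seq_along(key3)))
  expect_false(any(duplicated(idx3)))
  expect_error(subsample_balance(rep("a", 5)), "balance error")
})

test_that("word timing matrix holds first-occurrence onsets with NA sentinel", {
  st <- fixture_effects_study()
  wft <- build_word_timing_matrix(st)
  tr <- st$trials[!is.na(st$trials$release_time), ]
  expect_equal(nrow(wft$x), nrow(tr))
  expect_equal(wft$y, tr$release_time)
  # the target column holds the target onset where present
  tgt_rows <- !is.na(tr$target_onset)
  expect_equal(wft$x[tgt_rows, "word_0"], tr$target_onset[tgt_rows])
  # absent words are NA, not zero
  expect_true(anyNA(wft$x))
  expect_false(any(wft$x[!is.na(wft$x)] < 0))
  # first occurrence rule against a manual check on one trial
  id1 <- tr$trial_id[1]
  tk <- st$tokens[st$tokens$trial_id == id1, ]
  for (w in unique(tk$word_id)) {
    expect_equal(unname(wft$x[1, paste0("word_", w)]),
                 min(tk$onset[tk$word_id == w]))
  }
  # occurrence counts retained for duplicate diagnostics
  occ <- attr(wft, "occurrences")
  expect_true(any(occ$onset > 1))  # with-replacement sampling repeats words
})

test_that("frequency flattening equalizes per-word representation", {
  cfg <- session_config(n_trials = 800, vocab_size = 15, biased_words = 1,
                        bias_multiplier = 5)
  st <- generate_study(cfg, observer_params(), seed = 66)
  ids <- flatten_word_frequencies(st, floor = 30, n_cycles = 2, seed = 0)
  sel <- attr(ids, "selected_counts")
  expect_equal(max(sel) / min(sel), 1, tolerance = 0.2)
  # output indices are existing released trials only
  rel <- st$trials$trial_id[!is.na(st$trials$release_time)]
  expect_true(all(ids %in% rel))
  # log records availability and quotas
  lg <- attr(ids, "log")
  expect_true(all(c("word_id", "n_trials_available", "rows_selected") %in%
                  names(lg)))
  # the 5x-biased word is available in many more trials than the rest
  expect_gt(lg$n_trials_available[lg$word_id == 1],
            2 * stats::median(lg$n_trials_available[lg$word_id != 1]))
})

test_that("flattening on an already uniform corpus changes little", {
  st <- fixture_null_study()
  ids <- flatten_word_frequencies(st, floor = 25, n_cycles = 1, seed = 0)
  sel <- attr(ids, "selected_counts")
  prop <- sel / sum(sel)
  expect_lt(max(abs(prop - 1 / length(prop))) / (1 / length(prop)), 0.02)
})

test_that("high-frequency caps and cycle counts scale the output", {
  st <- fixture_null_study()
  ids1 <- flatten_word_frequencies(st, floor = 20, n_cycles = 1, seed = 4)
  ids3 <- flatten_word_frequencies(st, floor = 20, n_cycles = 3, seed = 4)
  expect_equal(length(ids3), 3 * length(ids1))
  # capped words contribute highfreq_cap rows per pass; cap 0 skips
  idsc <- flatten_word_frequencies(st, floor = 20, highfreq_words = c(1, 2),
                                   highfreq_cap = 5, n_cycles = 1, seed = 4)
  sel <- attr(idsc, "selected_counts")
  expect_equal(unname(sel[c("1", "2")]), c(10, 10))  # 2 passes x cap 5
  ids0 <- flatten_word_frequencies(st, floor = 20, highfreq_words = 1,
                                   highfreq_cap = 0, n_cycles = 1, seed = 4)
  expect_equal(unname(attr(ids0, "selected_counts")["1"]), 0)
})

test_that("duplicated trial ids expand the word-timing matrix", {
  st <- fixture_null_study()
  rel <- st$trials$trial_id[!is.na(st$trials$release_time)]
  ids <- c(rel[1], rel[1], rel[2])
  wft <- build_word_timing_matrix(st, trial_ids = ids)
  expect_equal(nrow(wft$x), 3)
  expect_equal(wft$x[1, ], wft$x[2, ])
})
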