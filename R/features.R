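#' Named feature sets for the four trial-level models
#'
#' Each model sees the covariate set of the analysis it belongs to:
#'
#' * `miss_hit` -- target trials only (hits and misses): talker, side,
#'   trial number, ferret, target presentation time, target F0, trial
#'   history flags, and whether the F0 of the non-target preceding the
#'   target matched the target F0.
#' * `false_alarm` -- all trials: talker, the trial F0 (for intra-roved
#'   trials the F0 of the last non-target word), side, trial duration, time
#'   elapsed in the trial, trial number, ferret, history flags, and an
#'   intra-rove indicator.
#' * `reaction_time` -- correct hits only: ferret, talker, target time,
#'   trial number, side, target F0, precursor-F0 match, history flags.
#' * `response_time` -- the per-word timing matrix built by
#'   [build_word_timing_matrix()].
#'
#' @param model_name one of `"miss_hit"`, `"false_alarm"`,
#'   `"reaction_time"`, `"response_time"`.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(model_name = c("miss_hit", "false_alarm",
                                        "reaction_time", "response_time")) {
  model_name <- match.arg(model_name)
  feats <- switch(model_name,
    miss_hit = c(talker = "categorical", side = "categorical",
                 trial_number = "numeric", ferret_id = "categorical",
                 target_time = "numeric", target_f0 = "categorical",
                 prev_was_catch = "flag", prev_was_correct = "flag",
                 precursor_match = "flag"),
    false_alarm = c(talker = "categorical", trial_f0 = "categorical",
                    side = "categorical", trial_duration = "numeric",
                    time_elapsed = "numeric", trial_number = "numeric",
                    ferret_id = "categorical", prev_was_correct = "flag",
                    prev_was_catch = "flag", intra_rove = "flag"),
    reaction_time = c(ferret_id = "categorical", talker = "categorical",
                      target_time = "numeric", trial_number = "numeric",
                      side = "categorical", target_f0 = "categorical",
                      precursor_match = "flag", prev_was_catch = "flag",
                      prev_was_correct = "flag"),
    response_time = c(word_onsets = "numeric"))
  structure(list(model_name = model_name, features = feats),
            class = "feature_spec")
}

# integer-code a categorical column, keeping the level table
.encode <- function(x) {
  f <- factor(x)
  list(values = as.numeric(f) - 1, levels = levels(f))
}

#' Build the model-ready feature table for a named model
#'
#' Encodes categoricals as integer codes (tree learners split on them
#' natively; level tables are kept in the column metadata), flags as 0/1,
#' and numerics as-is. Row filtering follows the model: `miss_hit` keeps
#' target trials that ended in a hit or miss (label: miss = 1),
#' `false_alarm` keeps every classified trial (label: false alarm = 1), and
#' `reaction_time` keeps hits (label: RT in seconds).
#'
#' @param study a `gng_study` (or a compatible list with `trials`).
#' @param spec a [feature_spec()] (or a model name).
#' @return an object of class `feature_table`: list with numeric matrix `x`,
#'   label `y`, `groups` (ferret), `meta` (per-feature type and levels) and
#'   the originating `spec`.
#' @export
build_features <- function(study, spec = feature_spec("miss_hit")) {
  if (is.character(spec)) spec <- feature_spec(spec)
  if (spec$model_name == "response_time")
    stop("use build_word_timing_matrix() for the response_time model")
  tr <- study$trials
  # a target with no preceding token breaks no pitch continuity: matched
  tr$precursor_match <- is.na(tr$precursor_f0) | tr$precursor_f0 == tr$target_f0
  tr$trial_f0 <- ifelse(tr$rove_mode == "intra", tr$last_nontarget_f0,
                        tr$stream_f0)
  tr$target_time <- tr$target_onset
  tr$time_elapsed <- ifelse(is.na(tr$release_time), tr$trial_duration,
                            tr$release_time)
  tr$intra_rove <- tr$rove_mode == "intra"

  keep <- switch(spec$model_name,
    miss_hit = tr$outcome %in% c("hit", "miss"),
    false_alarm = rep(TRUE, nrow(tr)),
    reaction_time = tr$outcome == "hit")
  tr <- tr[keep, , drop = FALSE]
  y <- switch(spec$model_name,
    miss_hit = as.numeric(tr$outcome == "miss"),
    false_alarm = as.numeric(tr$outcome == "false_alarm"),
    reaction_time = tr$rt)

  missing_cols <- setdiff(names(spec$features), names(tr))
  if (length(missing_cols))
    stop("schema error: features absent from records: ",
         paste(missing_cols, collapse = ", "))

  cols <- vector("list", length(spec$features))
  meta <- vector("list", length(spec$features))
  for (k in seq_along(spec$features)) {
    nm <- names(spec$features)[k]
    type <- spec$features[[k]]
    v <- tr[[nm]]
    if (type == "categorical") {
      e <- .encode(v)
      cols[[k]] <- e$values
      meta[[k]] <- list(feature = nm, type = type, levels = e$levels)
    } else if (type == "flag") {
      cols[[k]] <- as.numeric(v)
      meta[[k]] <- list(feature = nm, type = type, levels = c("no", "yes"))
    } else {
      cols[[k]] <- as.numeric(v)
      meta[[k]] <- list(feature = nm, type = type, levels = NULL)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(spec$features)
  structure(list(x = x, y = y, groups = tr$ferret_id,
                 trial_id = tr$trial_id, meta = meta, spec = spec),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d rows x %d features\n",
              x$spec$model_name, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Subsample rows to balance a key
#'
#' Returns row indices holding, for every level of `key`, the minimum level
#' count, sampled without replacement. Levels already at the minimum keep
#' all their rows, so an already balanced key returns every row. Indices
#' come back in increasing order (order-stable).
#'
#' @param key vector defining the levels to balance.
#' @param seed optional integer seed.
#' @return integer vector of retained row indices.
#' @export
subsample_balance <- function(key, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- table(key)
  if (length(tab) < 2) stop("balance error: key has a single level")
  m <- min(tab)
  idx <- unlist(lapply(names(tab), function(lv) {
    rows <- which(key == lv)
    if (length(rows) > m) sort(sample(rows, m)) else rows
  }))
  sort(idx)
}

#' Per-word timing matrix for the release-time model
#'
#' One column per vocabulary word (the target included as `word_0`), each
#' holding the onset, in seconds from trial onset, of that word's first
#' occurrence in the trial; words absent from a trial hold `NA`, the
#' missing-value sentinel tree learners handle natively (zero is a legal
#' onset, so it cannot stand for absence). The label is the release time
#' relative to trial onset; only trials with a release are used. Repeat
#' occurrence counts are kept in the `occurrences` attribute.
#'
#' @param study a `gng_study`.
#' @param talker optional talker filter (`"male"` / `"female"`), matching
#'   the per-talker response-time models.
#' @param trial_ids optional explicit trial subset (e.g. the output of
#'   [flatten_word_frequencies()]); duplicates are kept.
#' @return a `feature_table` whose `x` holds word onsets.
#' @export
build_word_timing_matrix <- function(study, talker = NULL,
                                     trial_ids = NULL) {
  vocab <- 0:study$config$vocab_size
  if (!length(vocab)) stop("schema error: empty vocabulary")
  tr <- study$trials
  keep <- !is.na(tr$release_time)
  if (!is.null(talker)) keep <- keep & tr$talker == talker
  tr <- tr[keep, , drop = FALSE]
  if (!is.null(trial_ids)) {
    if (anyNA(match(trial_ids, tr$trial_id)))
      stop("trial_ids refer to trials without a release")
  }
  tok <- study$tokens[study$tokens$trial_id %in% tr$trial_id, , drop = FALSE]
  # first-occurrence onset per (trial, word)
  first <- tok[order(tok$trial_id, tok$word_id, tok$onset), , drop = FALSE]
  dup <- duplicated(first[c("trial_id", "word_id")])
  occ <- stats::aggregate(onset ~ trial_id + word_id, tok, length)
  first <- first[!dup, , drop = FALSE]

  n <- nrow(tr)
  x <- matrix(NA_real_, n, length(vocab),
              dimnames = list(NULL, paste0("word_", vocab)))
  ri <- match(first$trial_id, tr$trial_id)
  ci <- match(first$word_id, vocab)
  ok <- !is.na(ri) & !is.na(ci)
  x[cbind(ri[ok], ci[ok])] <- first$onset[ok]
  if (!is.null(trial_ids)) {
    # expand to the requested multiset of trials (duplicates kept)
    pos <- match(trial_ids, tr$trial_id)
    x <- x[pos, , drop = FALSE]
    tr <- tr[pos, , drop = FALSE]
  }
  ft <- structure(list(x = x, y = tr$release_time, groups = tr$ferret_id,
                       trial_id = tr$trial_id,
                       meta = lapply(colnames(x), function(nm)
                         list(feature = nm, type = "numeric", levels = NULL)),
                       spec = feature_spec("response_time")),
                  class = "feature_table")
  attr(ft, "occurrences") <- occ
  ft
}

#' Frequency-flattening trial resampler
#'
#' Equalizes each word's guaranteed representation in the resampled trial
#' set: per cycle the vocabulary is walked first in order and then in
#' reverse, and for each word the trials containing it are subsampled
#' (without replacement within a pass) to `floor` rows -- or to
#' `highfreq_cap` rows for designated naturally high-frequency words
#' (`highfreq_cap = 0` skips them) -- and appended. Duplicates across passes
#' are permitted. The default of 19 cycles runs the forward-plus-reverse
#' walk once and repeats it 18 more times.
#'
#' @param study a `gng_study`.
#' @param floor rows selected per word per pass.
#' @param highfreq_words integer word ids treated as high-frequency.
#' @param highfreq_cap rows per pass for high-frequency words.
#' @param n_cycles number of forward+reverse cycles.
#' @param talker optional talker filter.
#' @param released_only keep only trials with a release (the rows the
#'   release-time model can use).
#' @param seed optional integer seed.
#' @return integer vector of trial ids (with repeats) for
#'   [build_word_timing_matrix()]; attributes `selected_counts` (rows
#'   selected per word -- the distribution the procedure flattens) and
#'   `log` (per-word trial availability before/after).
#' @export
flatten_word_frequencies <- function(study, floor = 700,
                                     highfreq_words = NULL,
                                     highfreq_cap = 50,
                                     n_cycles = 19,
                                     talker = NULL,
                                     released_only = TRUE,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- study$trials
  keep <- rep(TRUE, nrow(tr))
  if (released_only) keep <- !is.na(tr$release_time)
  if (!is.null(talker)) keep <- keep & tr$talker == talker
  ids <- tr$trial_id[keep]
  tok <- study$tokens
  tok <- tok[tok$trial_id %in% ids & tok$word_id > 0L, , drop = FALSE]
  words <- sort(unique(tok$word_id))
  by_word <- lapply(words, function(w) unique(tok$trial_id[tok$word_id == w]))
  names(by_word) <- words
  avail <- vapply(by_word, length, 0L)
  zero <- setdiff(seq_len(study$config$vocab_size), words)
  if (length(zero))
    warning("words with zero occurrences skipped: ",
            paste(zero, collapse = ", "))

  quota <- ifelse(words %in% highfreq_words, highfreq_cap, floor)
  out <- vector("list", n_cycles * 2L * length(words))
  sel_counts <- stats::setNames(numeric(length(words)), words)
  k <- 0L
  for (cyc in seq_len(n_cycles)) {
    for (ord in list(seq_along(words), rev(seq_along(words)))) {
      for (j in ord) {
        q <- quota[j]
        if (q == 0) next
        pool <- by_word[[j]]
        pick <- if (length(pool) > q) sample(pool, q) else pool
        k <- k + 1L
        out[[k]] <- pick
        sel_counts[j] <- sel_counts[j] + length(pick)
      }
    }
  }
  res <- unlist(out[seq_len(k)])
  attr(res, "selected_counts") <- sel_counts
  attr(res, "log") <- data.frame(word_id = words, n_trials_available = avail,
                                 quota_per_pass = quota,
                                 rows_selected = as.numeric(sel_counts))
  res
}
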