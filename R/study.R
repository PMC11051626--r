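#' Study-level configuration
#'
#' Bundles the generator, observer, training protocols and stage settings
#' of a full synthetic end-to-end analysis.
#'
#' @param session a [session_config()].
#' @param observer an [observer_params()].
#' @param protocol_cls classification [train_protocol()].
#' @param protocol_reg regression [train_protocol()].
#' @param balance balance labels (and rove levels) by subsampling before
#'   the cross-validation split.
#' @param flatten apply [flatten_word_frequencies()] before the word models
#'   (with `flatten_floor` rows per word per pass and `flatten_cycles`
#'   cycles).
#' @param flatten_floor,flatten_cycles resampler settings.
#' @param acoustics run the acoustic-similarity stage.
#' @param n_perm_repeats permutation-importance repeats.
#' @param seed master seed; per-stage seeds derive from it.
#' @export
study_config <- function(session = session_config(),
                         observer = observer_params(),
                         protocol_cls = train_protocol("binary"),
                         protocol_reg = train_protocol("regression"),
                         balance = TRUE,
                         flatten = TRUE,
                         flatten_floor = 700,
                         flatten_cycles = 19,
                         acoustics = TRUE,
                         n_perm_repeats = 10,
                         seed = 1) {
  structure(as.list(environment()), class = "study_config")
}

.stage_log <- function(manifest, stage, status, detail = "") {
  message(sprintf("[%s] %s %s", stage, status, detail))
  manifest$stages[[stage]] <- list(status = status, detail = detail)
  manifest
}

#' Per-word permutation importance of a release-time model
#'
#' Permutation importance (MSE drop) of each word-onset column, with the
#' word id parsed back from the column name.
#'
#' @param report a `gbm_report` fitted on a word-timing matrix.
#' @param n_repeats,seed passed to [permutation_importance()].
#' @export
word_importance <- function(report, n_repeats = 10, seed = 1) {
  pi <- permutation_importance(report, metric = "mse",
                               n_repeats = n_repeats, seed = seed)
  pi$word_id <- as.integer(sub("word_", "", pi$feature))
  pi
}

#' Run the five-model synthetic study end to end
#'
#' Generates a study with [generate_study()], then fits (1) the miss/hit
#' classifier, (2) the false-alarm classifier, (3) the reaction-time
#' regression, and (4--5) per-talker release-time word-attribution models,
#' each with balancing/flattening as configured; computes gain curves,
#' permutation importances and SHAP attributions; optionally links per-word
#' importance to acoustic similarity of synthesized tokens; and fits the
#' mixed-model and OLS baselines on the identical feature tables. A
#' manifest records every stage, seed and row count (and md5 hashes of any
#' artifacts written under `out_dir`); rerunning an identical configuration
#' reproduces identical artifacts.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return an object of class `study_result`: list of reports plus the
#'   manifest.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  manifest <- list(seed = config$seed, stages = list(), hashes = NULL)
  res <- list()

  manifest <- .stage_log(manifest, "simulate", "running",
                         sprintf("n_trials=%d seed=%d",
                                 config$session$n_trials, config$seed))
  study <- generate_study(config$session, config$observer,
                          seed = config$seed)
  res$study <- study
  manifest$stages$simulate$status <- "done"
  manifest$stages$simulate$n_trials <- nrow(study$trials)

  fit_cls <- function(name) {
    ft <- build_features(study, feature_spec(name))
    n0 <- nrow(ft$x)
    if (config$balance) {
      idx <- subsample_balance(ft$y, seed = config$seed)
      message(sprintf("[%s] balance: %d -> %d rows", name, n0, length(idx)))
      ft$x <- ft$x[idx, , drop = FALSE]
      ft$y <- ft$y[idx]
      ft$groups <- ft$groups[idx]
      ft$trial_id <- ft$trial_id[idx]
    }
    list(ft = ft, report = crossval_fit(ft, config$protocol_cls))
  }

  tryCatch({
    manifest <- .stage_log(manifest, "miss_hit", "running", "")
    mh <- fit_cls("miss_hit")
    res$miss_hit <- mh$report
    res$miss_hit_ft <- mh$ft
    manifest$stages$miss_hit$status <- "done"

    manifest <- .stage_log(manifest, "false_alarm", "running", "")
    fa <- fit_cls("false_alarm")
    res$false_alarm <- fa$report
    res$false_alarm_ft <- fa$ft
    manifest$stages$false_alarm$status <- "done"

    manifest <- .stage_log(manifest, "reaction_time", "running", "")
    rt_ft <- build_features(study, feature_spec("reaction_time"))
    res$reaction_time <- crossval_fit(rt_ft, config$protocol_reg)
    res$reaction_time_ft <- rt_ft
    manifest$stages$reaction_time$status <- "done"

    for (tk in c("female", "male")) {
      stage <- paste0("words_", tk)
      manifest <- .stage_log(manifest, stage, "running", "")
      ids <- NULL
      if (config$flatten) {
        ids <- flatten_word_frequencies(study, floor = config$flatten_floor,
                                        n_cycles = config$flatten_cycles,
                                        talker = tk, seed = config$seed)
        message(sprintf("[%s] flatten: %d rows selected", stage, length(ids)))
      }
      wft <- build_word_timing_matrix(study, talker = tk, trial_ids = ids)
      res[[stage]] <- crossval_fit(wft, config$protocol_reg)
      res[[paste0(stage, "_ft")]] <- wft
      manifest$stages[[stage]]$status <- "done"
    }

    manifest <- .stage_log(manifest, "attribution", "running", "")
    res$attribution <- list(
      miss_hit = list(
        gain = cumulative_gain_curve(res$miss_hit),
        permutation = permutation_importance(res$miss_hit,
                                             n_repeats = config$n_perm_repeats,
                                             seed = config$seed),
        shap = shap_attribution(res$miss_hit)),
      false_alarm = list(
        gain = cumulative_gain_curve(res$false_alarm),
        permutation = permutation_importance(res$false_alarm,
                                             n_repeats = config$n_perm_repeats,
                                             seed = config$seed),
        shap = shap_attribution(res$false_alarm)),
      reaction_time = list(
        gain = cumulative_gain_curve(res$reaction_time),
        permutation = permutation_importance(res$reaction_time,
                                             n_repeats = config$n_perm_repeats,
                                             seed = config$seed),
        shap = shap_attribution(res$reaction_time)),
      words_female = list(
        permutation = word_importance(res$words_female,
                                      n_repeats = config$n_perm_repeats,
                                      seed = config$seed)),
      words_male = list(
        permutation = word_importance(res$words_male,
                                      n_repeats = config$n_perm_repeats,
                                      seed = config$seed)))
    manifest$stages$attribution$status <- "done"

    if (config$acoustics) {
      manifest <- .stage_log(manifest, "acoustics", "running", "")
      target <- synth_word(word_spec(0), f0 = 191)
      toks <- lapply(seq_len(config$session$vocab_size), function(w)
        synth_word(word_spec(w), f0 = 191))
      sim <- token_similarity(toks, target)
      res$similarity <- sim
      res$similarity_link <- similarity_vs_importance(
        sim, res$attribution$words_female$permutation)
      manifest$stages$acoustics$status <- "done"
    } else {
      manifest <- .stage_log(manifest, "acoustics", "skipped",
                             "acoustics disabled in config")
    }

    manifest <- .stage_log(manifest, "baselines", "running", "")
    res$baselines <- list(
      miss_hit = fit_glmm_outcome(res$miss_hit_ft, seed = config$seed),
      false_alarm = fit_glmm_outcome(res$false_alarm_ft, seed = config$seed),
      reaction_time = fit_glmm_outcome(res$reaction_time_ft,
                                       family = "gaussian",
                                       seed = config$seed),
      ols_words_female = fit_ols_response_time(res$words_female_ft,
                                               fold = res$words_female$fold,
                                               seed = config$seed))
    manifest$stages$baselines$status <- "done"
  }, error = function(e) {
    manifest <<- .stage_log(manifest, "failed", "error", conditionMessage(e))
    warning("study stage failed; downstream stages skipped: ",
            conditionMessage(e))
  })

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_study(study, file.path(out_dir, "study"))
    for (nm in c("miss_hit", "false_alarm", "reaction_time")) {
      if (is.null(res[[nm]])) next
      utils::write.csv(res[[nm]]$metrics,
                       file.path(out_dir, paste0(nm, "_metrics.csv")),
                       row.names = FALSE)
      utils::write.csv(res$attribution[[nm]]$permutation,
                       file.path(out_dir, paste0(nm, "_permutation.csv")),
                       row.names = FALSE)
    }
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("manifest[.]json$", files)]
    manifest$hashes <- as.list(tools::md5sum(files))
    names(manifest$hashes) <- basename(names(manifest$hashes))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res$manifest <- manifest
  class(res) <- "study_result"
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result with stages:\n")
  for (nm in names(x$manifest$stages))
    cat(sprintf("  %-14s %s\n", nm, x$manifest$stages[[nm]]$status))
  invisible(x)
}
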