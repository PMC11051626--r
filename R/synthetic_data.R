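#' Configuration of the simulated word-stream task
#'
#' Defaults mirror the behavioral task being emulated: a 54-word non-target
#' vocabulary plus one target word, non-targets drawn with replacement,
#' target onset uniform on 0.5--6.5 s, 25% catch trials, at least 0.08 s of
#' silence between tokens, a 2 s response window, and talker-specific F0
#' triplets of {109, 124, 144} Hz (male) and {144, 191, 251} Hz (female).
#'
#' @param vocab_size number of non-target words.
#' @param catch_fraction proportion of catch trials.
#' @param target_window two-element vector, uniform support of target onset (s).
#' @param min_gap minimum inter-token silence (s).
#' @param gap_jitter width of the uniform jitter added above `min_gap` (s).
#' @param response_window response window (s).
#' @param talker_f0 named list mapping talker to a `(low, natural, high)` F0
#'   triplet in Hz.
#' @param rove_mix named proportions of `control`, `inter`, `intra` trials
#'   (must sum to 1).
#' @param word_duration_range log-uniform support of non-target token
#'   durations (s).
#' @param target_duration duration of the target token (s).
#' @param biased_words integer indices of non-target words sampled more often.
#' @param bias_multiplier relative frequency multiplier for `biased_words`.
#' @param n_trials number of trials to simulate.
#' @param n_ferrets number of subjects.
#' @param session_size trials per session, per subject.
#' @param seed optional integer seed used by [generate_study()].
#' @return an object of class `session_config`.
#' @export
session_config <- function(vocab_size = 54,
                           catch_fraction = 0.25,
                           target_window = c(0.5, 6.5),
                           min_gap = 0.08,
                           gap_jitter = 0.04,
                           response_window = 2,
                           talker_f0 = list(male = c(109, 124, 144),
                                            female = c(144, 191, 251)),
                           rove_mix = c(control = 0.5, inter = 0.25,
                                        intra = 0.25),
                           word_duration_range = c(0.25, 0.6),
                           target_duration = 0.55,
                           biased_words = NULL,
                           bias_multiplier = 1.8,
                           n_trials = 20000,
                           n_ferrets = 5,
                           session_size = 100,
                           seed = NULL) {
  stopifnot(vocab_size >= 1, catch_fraction >= 0, catch_fraction <= 1,
            length(target_window) == 2, target_window[1] < target_window[2],
            min_gap >= 0, gap_jitter >= 0, response_window > 0,
            length(word_duration_range) == 2,
            word_duration_range[1] > 0,
            word_duration_range[1] <= word_duration_range[2],
            n_trials >= 1, n_ferrets >= 1, session_size >= 1)
  if (abs(sum(rove_mix) - 1) > 1e-8 || any(rove_mix < 0))
    stop("rove_mix must be nonnegative proportions summing to 1")
  if (!all(c("control", "inter", "intra") %in% names(rove_mix)))
    stop("rove_mix must name control, inter and intra")
  if (!all(vapply(talker_f0, function(f) length(f) == 3 && all(f > 0), TRUE)))
    stop("each talker F0 set must hold 3 positive values")
  if (!is.null(biased_words) &&
      (any(biased_words < 1) || any(biased_words > vocab_size)))
    stop("biased_words out of vocabulary range")
  if (word_duration_range[1] + min_gap > target_window[1])
    stop("configuration error: word_duration_range incompatible with target window")
  structure(as.list(environment()), class = "session_config")
}

#' Parametric Go/No-Go observer
#'
#' The observer releases the centre port token by token: each pre-target
#' token carries a logistic release hazard (base log-odds plus per-ferret,
#' per-word-confusability, intra-rove and time-in-trial terms); the first
#' sampled release produces a false alarm at that token's onset plus a fixed
#' latency. If the target is reached it is detected with probability
#' `(1 - p_miss) * (1 - lapse_rate)`, where the miss log-odds combine
#' `qlogis(1 - detection_prob)` with talker and per-ferret terms. Detected
#' targets get a reaction time `rt_base` plus talker / F0 / precursor-F0
#' mismatch / target-time terms and truncated Gaussian noise, confined to
#' `(0, response_window]`.
#'
#' All effect parameters default to zero so the default observer is a
#' well-trained, unbiased animal; studies inject effects explicitly.
#'
#' @param base_fa_hazard per-token release log-odds.
#' @param word_confusability named numeric vector of per-word hazard offsets
#'   (names are vocabulary indices as character).
#' @param intra_rove_fa_offset hazard offset (log-odds) on intra-roved trials.
#' @param fa_talker_effect hazard offset for the male talker.
#' @param fa_time_slope hazard change per second of token onset.
#' @param fa_latency latency from triggering token onset to release (s).
#' @param detection_prob baseline probability of detecting the target.
#' @param miss_talker_effect added miss log-odds for the male talker.
#' @param ferret_fa,ferret_miss,ferret_rt per-ferret intercepts (recycled to
#'   the number of ferrets).
#' @param lapse_rate probability of missing regardless of detection.
#' @param rt_base baseline reaction time (s).
#' @param rt_talker_effect added RT for the male talker (s).
#' @param rt_f0_effects named numeric vector, added RT by target F0 (Hz, s).
#' @param rt_precursor_mismatch_effect added RT when the token preceding the
#'   target differs from it in F0 (s).
#' @param rt_target_time_slope RT change per second of target onset (s/s).
#' @param rt_noise_sd SD of Gaussian RT noise (s).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(base_fa_hazard = -4,
                            word_confusability = NULL,
                            intra_rove_fa_offset = 0,
                            fa_talker_effect = 0,
                            fa_time_slope = 0,
                            fa_latency = 0.25,
                            detection_prob = 0.9,
                            miss_talker_effect = 0,
                            ferret_fa = 0,
                            ferret_miss = 0,
                            ferret_rt = 0,
                            lapse_rate = 0.02,
                            rt_base = 0.45,
                            rt_talker_effect = 0,
                            rt_f0_effects = NULL,
                            rt_precursor_mismatch_effect = 0,
                            rt_target_time_slope = 0,
                            rt_noise_sd = 0.15) {
  stopifnot(detection_prob >= 0, detection_prob <= 1,
            lapse_rate >= 0, lapse_rate <= 1,
            rt_noise_sd >= 0, fa_latency >= 0,
            is.finite(base_fa_hazard), is.finite(intra_rove_fa_offset))
  if (!is.null(word_confusability) && any(!is.finite(word_confusability)))
    stop("word_confusability hazards must be finite")
  structure(as.list(environment()), class = "observer_params")
}

# sample a non-target word index, respecting frequency bias
.word_probs <- function(config) {
  w <- rep(1, config$vocab_size)
  if (!is.null(config$biased_words))
    w[config$biased_words] <- config$bias_multiplier
  w / sum(w)
}

#' Build one word-token stream
#'
#' Lays out non-target tokens from trial onset, places the target (or, on
#' catch trials, a duration-matched extra non-target at a virtual target
#' time, so catch and target trials match in duration distribution), and
#' extends the stream with trailing non-targets until at least one response
#' window past the (virtual) target onset. Token F0s follow the rove mode:
#' `control` uses the talker's natural F0 for every token, `inter` shifts
#' every token to the talker's low or high F0, and `intra` draws each
#' token's F0 independently from the talker's three F0s.
#'
#' @param config a [session_config()].
#' @param talker `"male"` or `"female"`.
#' @param rove_mode `"control"`, `"inter"` or `"intra"`.
#' @param is_catch logical; catch streams contain no target token.
#' @return a list with `tokens` (data frame: `word_id`, `onset`, `duration`,
#'   `f0`, `is_target`; `word_id` 0 is the target), `target_onset` (`NA` on
#'   catch trials) and `trial_duration`. Uses the R RNG; seed with
#'   [set.seed()] for reproducibility.
#' @export
build_stream <- function(config, talker = "male", rove_mode = "control",
                         is_catch = FALSE) {
  stopifnot(inherits(config, "session_config"),
            talker %in% names(config$talker_f0),
            rove_mode %in% c("control", "inter", "intra"))
  probs <- .word_probs(config)
  dr <- log(config$word_duration_range)
  draw_dur <- function(n) exp(stats::runif(n, dr[1], dr[2]))
  target_time <- stats::runif(1, config$target_window[1],
                              config$target_window[2])

  word_id <- integer(0); onset <- numeric(0); duration <- numeric(0)
  cur <- 0
  # leading non-targets: place while the next token still fits before the
  # target slot with at least min_gap of silence
  repeat {
    d <- draw_dur(1)
    if (cur + d + config$min_gap > target_time) break
    word_id <- c(word_id, sample.int(config$vocab_size, 1, prob = probs))
    onset <- c(onset, cur)
    duration <- c(duration, d)
    cur <- cur + d + config$min_gap + stats::runif(1, 0, config$gap_jitter)
  }
  # the target slot (a duration-matched non-target on catch trials)
  slot_dur <- if (is_catch) draw_dur(1) else config$target_duration
  word_id <- c(word_id,
               if (is_catch) sample.int(config$vocab_size, 1, prob = probs)
               else 0L)
  onset <- c(onset, target_time)
  duration <- c(duration, slot_dur)
  cur <- target_time + slot_dur + config$min_gap +
    stats::runif(1, 0, config$gap_jitter)
  # trailing non-targets must outlast the response window
  while (max(onset + duration) < target_time + config$response_window) {
    d <- draw_dur(1)
    word_id <- c(word_id, sample.int(config$vocab_size, 1, prob = probs))
    onset <- c(onset, cur)
    duration <- c(duration, d)
    cur <- cur + d + config$min_gap + stats::runif(1, 0, config$gap_jitter)
  }
  n <- length(word_id)
  f0_set <- config$talker_f0[[talker]]
  f0 <- switch(rove_mode,
               control = rep(f0_set[2], n),
               inter = rep(f0_set[sample(c(1, 3), 1)], n),
               intra = f0_set[sample.int(3, n, replace = TRUE)])
  list(tokens = data.frame(word_id = word_id, onset = onset,
                           duration = duration, f0 = f0,
                           is_target = !is_catch & word_id == 0L),
       target_onset = if (is_catch) NA_real_ else target_time,
       trial_duration = max(onset + duration))
}

#' Simulate the observer's response to one stream
#'
#' @param stream a stream as returned by [build_stream()].
#' @param params an [observer_params()].
#' @param talker,rove_mode trial covariates.
#' @param ferret integer subject index (selects per-ferret intercepts).
#' @param config the [session_config()] (for the response window).
#' @return list with `release_time` (`NA` if the port was held) and the
#'   realized `rt` for detected targets (`NA` otherwise).
#' @export
simulate_observer <- function(stream, params, talker, rove_mode, ferret,
                              config) {
  stopifnot(inherits(params, "observer_params"))
  tok <- stream$tokens
  tgt <- stream$target_onset
  f_fa <- rep_len(params$ferret_fa, max(ferret, 1))[ferret]
  f_miss <- rep_len(params$ferret_miss, max(ferret, 1))[ferret]
  f_rt <- rep_len(params$ferret_rt, max(ferret, 1))[ferret]

  pre <- if (is.na(tgt)) seq_len(nrow(tok)) else which(tok$onset < tgt & !tok$is_target)
  if (length(pre)) {
    confus <- numeric(length(pre))
    if (!is.null(params$word_confusability)) {
      m <- match(as.character(tok$word_id[pre]),
                 names(params$word_confusability))
      confus[!is.na(m)] <- params$word_confusability[m[!is.na(m)]]
    }
    eta <- params$base_fa_hazard + f_fa + confus +
      params$intra_rove_fa_offset * (rove_mode == "intra") +
      params$fa_talker_effect * (talker == "male") +
      params$fa_time_slope * tok$onset[pre]
    rel <- stats::runif(length(pre)) < stats::plogis(eta)
    if (any(rel)) {
      j <- pre[which(rel)[1]]
      release <- min(tok$onset[j] + params$fa_latency, stream$trial_duration)
      return(list(release_time = release, rt = NA_real_))
    }
  }
  if (is.na(tgt)) return(list(release_time = NA_real_, rt = NA_real_))

  miss_lo <- stats::qlogis(min(max(1 - params$detection_prob, 1e-12), 1 - 1e-12)) +
    params$miss_talker_effect * (talker == "male") + f_miss
  detected <- (stats::runif(1) >= stats::plogis(miss_lo)) &&
    (stats::runif(1) >= params$lapse_rate)
  if (!detected) return(list(release_time = NA_real_, rt = NA_real_))

  i_t <- which(tok$is_target)
  prev <- which(tok$onset < tgt)
  precursor_f0 <- if (length(prev)) tok$f0[max(prev)] else tok$f0[i_t]
  f0_eff <- 0
  if (!is.null(params$rt_f0_effects)) {
    m <- match(as.character(tok$f0[i_t]), names(params$rt_f0_effects))
    if (!is.na(m)) f0_eff <- params$rt_f0_effects[m]
  }
  mu <- params$rt_base + f_rt +
    params$rt_talker_effect * (talker == "male") + f0_eff +
    params$rt_precursor_mismatch_effect * (precursor_f0 != tok$f0[i_t]) +
    params$rt_target_time_slope * tgt
  rt <- mu + stats::rnorm(1, 0, params$rt_noise_sd)
  tries <- 0
  while ((rt <= 0 || rt > config$response_window) && tries < 50) {
    rt <- mu + stats::rnorm(1, 0, params$rt_noise_sd)
    tries <- tries + 1
  }
  rt <- unname(min(max(rt, 1e-3), config$response_window))
  list(release_time = tgt + rt, rt = rt)
}

#' Simulate a full behavioral study
#'
#' Generates `config$n_trials` sequential trials across subjects and
#' sessions, builds each word stream, simulates the observer, classifies
#' outcomes and fills trial-history flags (`prev_was_catch`,
#' `prev_was_correct`) from the realized per-ferret trial sequence.
#'
#' @param config a [session_config()].
#' @param params an [observer_params()].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return an object of class `gng_study`: list with `trials` (one row per
#'   trial) and `tokens` (long token table keyed by `trial_id`), plus the
#'   generating `config` and `params`.
#' @export
generate_study <- function(config = session_config(),
                           params = observer_params(),
                           seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  talkers <- sample(c("male", "female"), n, replace = TRUE)
  sides <- sample(c("left", "right"), n, replace = TRUE)
  roves <- sample(names(config$rove_mix), n, replace = TRUE,
                  prob = config$rove_mix)
  catches <- stats::runif(n) < config$catch_fraction
  ferrets <- sample.int(config$n_ferrets, n, replace = TRUE)

  cols <- list(trial_id = integer(n), ferret_id = character(n),
               talker = character(n), side = character(n),
               session_id = character(n), trial_number = integer(n),
               rove_mode = character(n), trial_duration = numeric(n),
               target_onset = numeric(n), target_f0 = numeric(n),
               stream_f0 = numeric(n), precursor_f0 = numeric(n),
               last_nontarget_f0 = numeric(n), n_tokens = integer(n),
               release_time = numeric(n), rt = numeric(n),
               prev_was_catch = logical(n), prev_was_correct = logical(n),
               outcome = character(n))
  tok_acc <- list(word_id = vector("list", n), onset = vector("list", n),
                  duration = vector("list", n), f0 = vector("list", n),
                  is_target = vector("list", n))
  tok_len <- integer(n)
  trial_count <- integer(config$n_ferrets)
  last_catch <- rep(FALSE, config$n_ferrets)
  last_correct <- rep(TRUE, config$n_ferrets)

  for (i in seq_len(n)) {
    fer <- ferrets[i]
    stream <- build_stream(config, talkers[i], roves[i], catches[i])
    resp <- simulate_observer(stream, params, talkers[i], roves[i], fer,
                              config)
    tok <- stream$tokens
    out <- classify_outcome(stream$target_onset, resp$release_time,
                            stream$trial_duration, config$response_window)
    trial_count[fer] <- trial_count[fer] + 1L
    nt <- which(!tok$is_target)
    i_t <- which(tok$is_target)
    prev <- if (length(i_t)) which(tok$onset < tok$onset[i_t]) else integer(0)

    cols$trial_id[i] <- i
    cols$ferret_id[i] <- sprintf("F%02d", fer)
    cols$talker[i] <- talkers[i]
    cols$side[i] <- sides[i]
    cols$session_id[i] <- sprintf("F%02d_S%03d", fer,
                                  (trial_count[fer] - 1L) %/% config$session_size + 1L)
    cols$trial_number[i] <- (trial_count[fer] - 1L) %% config$session_size + 1L
    cols$rove_mode[i] <- roves[i]
    cols$trial_duration[i] <- stream$trial_duration
    cols$target_onset[i] <- stream$target_onset
    cols$target_f0[i] <- if (length(i_t)) tok$f0[i_t] else NA_real_
    cols$stream_f0[i] <- if (roves[i] == "intra") NA_real_ else tok$f0[1]
    cols$precursor_f0[i] <- if (length(prev)) tok$f0[max(prev)] else NA_real_
    cols$last_nontarget_f0[i] <- if (length(nt)) tok$f0[max(nt)] else NA_real_
    cols$n_tokens[i] <- nrow(tok)
    cols$release_time[i] <- resp$release_time
    cols$rt[i] <- resp$rt
    cols$prev_was_catch[i] <- last_catch[fer]
    cols$prev_was_correct[i] <- last_correct[fer]
    cols$outcome[i] <- out

    last_catch[fer] <- catches[i]
    last_correct[fer] <- out %in% c("hit", "correct_rejection")
    tok_len[i] <- nrow(tok)
    for (cc in names(tok_acc)) tok_acc[[cc]][[i]] <- tok[[cc]]
  }
  trials <- as.data.frame(cols, stringsAsFactors = FALSE)
  tokens <- data.frame(trial_id = rep.int(seq_len(n), tok_len),
                       word_id = unlist(tok_acc$word_id),
                       onset = unlist(tok_acc$onset),
                       duration = unlist(tok_acc$duration),
                       f0 = unlist(tok_acc$f0),
                       is_target = unlist(tok_acc$is_target))
  structure(list(trials = trials, tokens = tokens, config = config,
                 params = params, seed = seed),
            class = "gng_study")
}

#' @export
print.gng_study <- function(x, ...) {
  cat(sprintf("gng_study: %d trials, %d tokens, %d ferrets\n",
              nrow(x$trials), nrow(x$tokens),
              length(unique(x$trials$ferret_id))))
  print(session_metrics(x$trials$outcome))
  invisible(x)
}

#' Write / read a study as delimited text
#'
#' The trial and token tables go to `trials.csv` and `tokens.csv`; a sidecar
#' `schema.json` names the columns of each file.
#'
#' @param study a `gng_study`.
#' @param dir output directory (created if missing).
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(study$tokens, file.path(dir, "tokens.csv"),
                   row.names = FALSE)
  schema <- list(trials = names(study$trials), tokens = names(study$tokens),
                 seed = study$seed)
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  tokens <- utils::read.csv(file.path(dir, "tokens.csv"),
                            stringsAsFactors = FALSE)
  structure(list(trials = trials, tokens = tokens, config = NULL,
                 params = NULL, seed = NULL), class = "gng_study")
}
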