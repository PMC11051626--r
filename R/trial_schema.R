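#' Classify single-trial outcomes of a Go/No-Go word-stream task
#'
#' A trial ends in one of four outcomes. On target trials, a release of the
#' centre port within the response window after target onset is a `hit`;
#' holding through the window (or releasing after it closes) is a `miss`.
#' A release strictly before target onset -- or any release on a catch trial,
#' which contains no target -- is a `false_alarm`; a catch trial with no
#' release is a `correct_rejection`. The window is half-open: a release at
#' exactly the target onset still counts as a false alarm.
#'
#' @param target_onset numeric vector, seconds from trial onset; `NA` marks a
#'   catch trial.
#' @param release_time numeric vector, centre-port release time in seconds
#'   from trial onset; `NA` if the animal held for the whole trial.
#' @param trial_duration numeric vector, total trial duration in seconds.
#' @param response_window scalar, response window in seconds (default 2).
#' @return character vector with levels `hit`, `miss`, `false_alarm`,
#'   `correct_rejection`.
#' @examples
#' classify_outcome(3, 4.2, 8)                 # hit
#' classify_outcome(NA_real_, NA_real_, 8)     # correct_rejection
#' @export
classify_outcome <- function(target_onset, release_time, trial_duration,
                             response_window = 2) {
  stopifnot(is.numeric(response_window), length(response_window) == 1L,
            response_window > 0)
  n <- max(length(target_onset), length(release_time), length(trial_duration))
  target_onset <- rep_len(target_onset, n)
  release_time <- rep_len(release_time, n)
  trial_duration <- rep_len(trial_duration, n)
  if (any(release_time > trial_duration, na.rm = TRUE))
    stop("invalid record: release_time exceeds trial_duration")
  if (any(c(target_onset, release_time, trial_duration) < 0, na.rm = TRUE))
    stop("invalid record: negative times")
  is_catch <- is.na(target_onset)
  released <- !is.na(release_time)
  out <- character(n)
  out[is_catch & !released] <- "correct_rejection"
  out[is_catch & released] <- "false_alarm"
  tt <- !is_catch
  hit <- tt & released & release_time > target_onset &
    release_time <= target_onset + response_window
  fa <- tt & released & release_time <= target_onset
  out[tt] <- "miss"  # includes releases after the window closed
  out[hit] <- "hit"
  out[fa] <- "false_alarm"
  out
}

#' Chance proportion correct for a hold-and-release task
#'
#' With a uniformly timed target inside a trial of fixed duration and a
#' release window of `response_window` seconds, a random single release is
#' correct with probability `response_window / trial_duration` (e.g. a 2 s
#' window in a 6 s trial gives 1/3).
#'
#' @param trial_duration trial duration in seconds.
#' @param response_window response window in seconds.
#' @return chance proportion correct.
#' @export
chance_level <- function(trial_duration, response_window) {
  if (any(trial_duration <= 0) || any(response_window <= 0))
    stop("invalid argument: durations must be positive")
  if (any(response_window > trial_duration))
    stop("invalid argument: response_window exceeds trial_duration")
  response_window / trial_duration
}

#' Sensitivity (d-prime) from hit and false-alarm rates
#'
#' `d' = qnorm(p_hit) - qnorm(p_fa)`. Rates of exactly 0 or 1 are clipped to
#' `1/(2N)` and `1 - 1/(2N)` (the standard correction) when the relevant
#' trial count is supplied, otherwise to `clip`.
#'
#' @param p_hit,p_fa proportions in `[0, 1]`.
#' @param n_signal,n_noise trial counts behind each proportion (optional).
#' @param clip fallback clipping bound when counts are unknown.
#' @export
d_prime <- function(p_hit, p_fa, n_signal = NULL, n_noise = NULL,
                    clip = 1e-4) {
  clip_rate <- function(p, n) {
    lo <- if (!is.null(n)) 1 / (2 * n) else clip
    pmin(pmax(p, lo), 1 - lo)
  }
  stats::qnorm(clip_rate(p_hit, n_signal)) - stats::qnorm(clip_rate(p_fa, n_noise))
}

#' Session-level performance summary
#'
#' Counts outcomes and derives `p(hit) = hits / (hits + misses)`,
#' `p(FA) = FA / total`, `p(correct) = (hits + CR) / total` and d-prime,
#' following standard Go/No-Go conventions.
#'
#' @param outcomes character vector of outcome labels as produced by
#'   [classify_outcome()].
#' @return an object of class `session_summary`: a list with counts,
#'   proportions, `d_prime`, and an `undefined` flag naming any metric whose
#'   denominator was zero.
#' @export
session_metrics <- function(outcomes) {
  bad <- setdiff(unique(outcomes),
                 c("hit", "miss", "false_alarm", "correct_rejection"))
  if (length(bad)) stop("unknown outcome labels: ", paste(bad, collapse = ", "))
  n_hits <- sum(outcomes == "hit")
  n_misses <- sum(outcomes == "miss")
  n_fa <- sum(outcomes == "false_alarm")
  n_cr <- sum(outcomes == "correct_rejection")
  total <- n_hits + n_misses + n_fa + n_cr
  undefined <- character(0)
  if (total == 0) stop("undefined metric: no classified trials")
  n_target <- n_hits + n_misses
  p_hit <- if (n_target > 0) n_hits / n_target else {
    undefined <- c(undefined, "p_hit", "d_prime"); NA_real_
  }
  p_fa <- n_fa / total
  p_correct <- (n_hits + n_cr) / total
  dp <- if (n_target > 0) d_prime(p_hit, p_fa, n_target, total) else NA_real_
  structure(list(n_hits = n_hits, n_misses = n_misses, n_fa = n_fa,
                 n_cr = n_cr, n_trials = total, p_hit = p_hit, p_fa = p_fa,
                 p_correct = p_correct, d_prime = dp, undefined = undefined),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("Go/No-Go session: %d trials (%d hit, %d miss, %d FA, %d CR)\n",
              x$n_trials, x$n_hits, x$n_misses, x$n_fa, x$n_cr))
  cat(sprintf("  p(hit) = %.3f  p(FA) = %.3f  p(correct) = %.3f  d' = %.2f\n",
              x$p_hit, x$p_fa, x$p_correct, x$d_prime))
  invisible(x)
}

#' Reaction time and response time
#'
#' Reaction time is the centre-port release time relative to target onset
#' (defined for hits); response time is the release time relative to trial
#' onset (defined whenever a release occurred, including false alarms).
#'
#' @param trials a trial table (data frame with `target_onset`,
#'   `release_time`, `outcome` columns), e.g. the `$trials` component of
#'   [generate_study()].
#' @return numeric vector in seconds; `NA` where undefined.
#' @export
reaction_time <- function(trials) {
  if (all(is.na(trials$target_onset)))
    stop("undefined metric: reaction time requested on catch trials only")
  rt <- trials$release_time - trials$target_onset
  rt[trials$outcome != "hit"] <- NA_real_
  rt
}

#' @rdname reaction_time
#' @export
response_time <- function(trials) {
  trials$release_time
}
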