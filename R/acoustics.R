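#' Word template for the synthetic token generator
#'
#' A word is modelled source--filter style: a harmonic complex at the voice
#' F0, spectrally shaped by 2--3 word-specific resonances (formant-like
#' peaks), under a word-specific multi-bump amplitude envelope (syllables).
#' Templates are drawn deterministically from `word_id` via a seeded RNG, so
#' the same id always yields the same spectrotemporal shape; F0 changes move
#' the fine structure but not the template.
#'
#' @param word_id integer id (0 is conventionally the target word).
#' @param n_formants number of resonances (2 or 3; drawn if `NULL`).
#' @param duration token duration in seconds (drawn in 0.25--0.6 if `NULL`).
#' @param seed base seed combined with `word_id`.
#' @return an object of class `word_spec` (formant centre frequencies and
#'   bandwidths in Hz, envelope bump positions/widths, duration).
#' @export
word_spec <- function(word_id, n_formants = NULL, duration = NULL,
                      seed = 1000) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + word_id)
  if (is.null(n_formants)) n_formants <- sample(2:3, 1)
  formants <- sort(stats::runif(n_formants, 400, 3800))
  bw <- stats::runif(n_formants, 80, 200)
  if (is.null(duration)) duration <- exp(stats::runif(1, log(0.25), log(0.6)))
  n_bumps <- sample(1:3, 1)
  bump_pos <- sort(stats::runif(n_bumps, 0.15, 0.85))
  bump_width <- stats::runif(n_bumps, 0.08, 0.2)
  bump_amp <- stats::runif(n_bumps, 0.6, 1)
  structure(list(word_id = word_id, formants = formants, bw = bw,
                 duration = duration, bump_pos = bump_pos,
                 bump_width = bump_width, bump_amp = bump_amp),
            class = "word_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize a word token at a given F0
#'
#' Additive harmonic synthesis: harmonics of `f0` up to 5 kHz, each weighted
#' by the template's resonance gains evaluated at the harmonic frequency,
#' multiplied by the template's amplitude envelope and peak-normalized.
#' Deterministic: the same spec, F0 and rate always give the same samples.
#'
#' @param spec a [word_spec()].
#' @param f0 fundamental frequency in Hz (must be below `sample_rate / 4`).
#' @param sample_rate sampling rate in Hz.
#' @param duration optional override of the template duration (s).
#' @return an object of class `token_audio`: list with `samples`,
#'   `sample_rate`, `word_id`, `f0`, `duration`.
#' @export
synth_word <- function(spec, f0, sample_rate = 24414, duration = NULL) {
  if (is.null(duration)) duration <- spec$duration
  if (duration <= 0) stop("invalid argument: nonpositive duration")
  if (f0 >= sample_rate / 4) stop("invalid argument: f0 must be < sample_rate/4")
  n <- round(duration * sample_rate)
  t <- seq_len(n) / sample_rate
  f_max <- min(5000, sample_rate / 2 * 0.9)
  harmonics <- seq(f0, f_max, by = f0)
  # resonance gain: sum of Lorentzian peaks at the formant frequencies
  gain <- function(f) {
    g <- 0
    for (k in seq_along(spec$formants))
      g <- g + 1 / (1 + ((f - spec$formants[k]) / spec$bw[k])^2)
    g + 0.01
  }
  wave <- numeric(n)
  for (h in harmonics)
    wave <- wave + gain(h) * sin(2 * pi * h * t)
  env <- numeric(n)
  frac <- t / duration
  for (b in seq_along(spec$bump_pos))
    env <- env + spec$bump_amp[b] *
      exp(-0.5 * ((frac - spec$bump_pos[b]) / spec$bump_width[b])^2)
  wave <- wave * env
  wave <- wave / max(abs(wave))
  structure(list(samples = wave, sample_rate = sample_rate,
                 word_id = spec$word_id, f0 = f0, duration = duration),
            class = "token_audio")
}

# analytic signal magnitude via the frequency-domain Hilbert construction
.analytic_magnitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

.resample_series <- function(x, rate_in, rate_out) {
  n_out <- max(2L, round(length(x) / rate_in * rate_out))
  stats::approx(seq_along(x) / rate_in, x,
                xout = seq_len(n_out) / rate_out, rule = 2)$y
}

#' Amplitude envelope of a token
#'
#' Magnitude of the analytic signal, low-passed (Butterworth, zero-phase)
#' at `cutoff` and resampled to a common envelope rate.
#'
#' @param audio a `token_audio` (or numeric samples with `sample_rate`).
#' @param cutoff low-pass cutoff in Hz.
#' @param env_rate output envelope sampling rate in Hz.
#' @param sample_rate required when `audio` is a bare numeric vector.
#' @return numeric envelope series (nonnegative) with attribute `rate`.
#' @export
extract_envelope <- function(audio, cutoff = 30, env_rate = 1000,
                             sample_rate = NULL) {
  if (inherits(audio, "token_audio")) {
    x <- audio$samples; sr <- audio$sample_rate
  } else { x <- audio; sr <- sample_rate }
  if (is.null(sr)) stop("sample_rate required")
  if (length(x) < 16) stop("short-signal error: audio shorter than filter warm-up")
  env <- .analytic_magnitude(x)
  bf <- signal::butter(4, cutoff / (sr / 2), type = "low")
  env <- signal::filtfilt(bf, env)
  env <- pmax(env, 0)
  out <- .resample_series(env, sr, env_rate)
  attr(out, "rate") <- env_rate
  out
}

# ERB-rate spaced centre frequencies (Glasberg & Moore constants)
erb_space <- function(f_lo, f_hi, n) {
  ear_q <- 9.26449; min_bw <- 24.7
  pts <- seq(0, 1, length.out = n)
  lo <- log(f_lo / ear_q + min_bw); hi <- log(f_hi / ear_q + min_bw)
  ear_q * (exp(lo + pts * (hi - lo)) - min_bw)
}

erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Cochleagram of a token
#'
#' A peripheral-auditory time--frequency representation: an ERB-spaced
#' 4th-order gammatone filterbank, half-wave rectification, low-pass
#' smoothing, compressive (cube-root) nonlinearity, and downsampling to a
#' common frame rate. Channel centre frequencies increase strictly; all
#' entries are nonnegative. Note this mirrors a human peripheral model,
#' which likely overestimates the spectral resolution of smaller mammals.
#'
#' @param audio a `token_audio` or numeric samples.
#' @param n_channels number of gammatone channels (>= 2).
#' @param f_range two-element frequency range in Hz, inside
#'   `(0, sample_rate/2)`.
#' @param frame_rate output frame rate in Hz.
#' @param compression exponent of the compressive nonlinearity.
#' @param sample_rate required for bare numeric input.
#' @return matrix `n_channels x n_frames` with attributes `cf` (centre
#'   frequencies) and `frame_rate`.
#' @export
cochleagram <- function(audio, n_channels = 64, f_range = c(50, 8000),
                        frame_rate = 100, compression = 1 / 3,
                        sample_rate = NULL) {
  if (inherits(audio, "token_audio")) {
    x <- audio$samples; sr <- audio$sample_rate
  } else { x <- audio; sr <- sample_rate }
  if (is.null(sr)) stop("sample_rate required")
  if (n_channels < 2) stop("configuration error: n_channels must be >= 2")
  if (f_range[1] <= 0 || f_range[2] >= sr / 2)
    stop("configuration error: f_range outside (0, sample_rate/2)")
  cf <- erb_space(f_range[1], f_range[2], n_channels)
  n <- length(x)
  # FFT-domain gammatone filtering: one forward transform of the signal,
  # one frequency response per channel
  nfft <- stats::nextn(n + round(0.03 * sr), 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  t_ir <- seq_len(round(0.03 * sr)) / sr
  bf <- signal::butter(2, min(frame_rate, sr / 4) / (sr / 2), type = "low")
  out <- matrix(0, n_channels, 0)
  frames <- NULL
  for (ch in seq_len(n_channels)) {
    b <- 1.019 * erb_bandwidth(cf[ch])
    ir <- t_ir^3 * exp(-2 * pi * b * t_ir) * cos(2 * pi * cf[ch] * t_ir)
    IR <- stats::fft(c(ir, numeric(nfft - length(ir))))
    # normalize to unit peak magnitude response
    IR <- IR / max(Mod(IR))
    y <- Re(stats::fft(X * IR, inverse = TRUE) / nfft)[seq_len(n)]
    y <- pmax(y, 0)
    y <- signal::filtfilt(bf, y)
    y <- pmax(y, 0)^compression
    fr <- .resample_series(y, sr, frame_rate)
    if (is.null(frames)) {
      frames <- length(fr)
      out <- matrix(0, n_channels, frames)
    }
    out[ch, ] <- fr
  }
  attr(out, "cf") <- cf
  attr(out, "frame_rate") <- frame_rate
  out
}

# truncate two series/matrices to a common time length
.common_time <- function(a, b) {
  ta <- if (is.matrix(a)) ncol(a) else length(a)
  tb <- if (is.matrix(b)) ncol(b) else length(b)
  n <- min(ta, tb)
  cut <- function(z) if (is.matrix(z)) z[, seq_len(n), drop = FALSE] else z[seq_len(n)]
  list(a = cut(a), b = cut(b), n = n)
}

#' Onset-aligned Pearson correlation of two series or cochleagrams
#'
#' Both inputs are truncated to the shorter duration and correlated point
#' by point; matrices (channel x time, on the same channel grid) are
#' compared cell by cell after truncation.
#'
#' @param a,b numeric series or matrices at the same rate / channel grid.
#' @return Pearson r in `[-1, 1]`; `NA` with a warning for zero-variance
#'   input.
#' @export
onset_corr <- function(a, b) {
  z <- .common_time(a, b)
  va <- as.vector(z$a); vb <- as.vector(z$b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("undefined correlation: zero-variance input")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Maximum normalized cross-correlation over time lags
#'
#' Slides the shorter input over the longer along the time axis (channels
#' stay aligned for matrices) and returns the maximum Pearson correlation
#' over all window positions, including partial overlaps of at least
#' `min_overlap` of the shorter duration. Acknowledges that any portion of
#' one token may be confused with any portion of another.
#'
#' @param a,b series or matrices at the same rate / channel grid.
#' @param min_overlap minimum overlap fraction of the shorter input.
#' @return maximum correlation in `[-1, 1]`, with attribute `lag` (frames).
#' @export
max_xcorr <- function(a, b, min_overlap = 0.5) {
  ta <- if (is.matrix(a)) ncol(a) else length(a)
  tb <- if (is.matrix(b)) ncol(b) else length(b)
  if (ta > tb) return(max_xcorr(b, a, min_overlap))
  short <- a; long <- b
  ns <- ta; nl <- tb
  win <- function(z, i, len) if (is.matrix(z)) z[, i:(i + len - 1), drop = FALSE] else z[i:(i + len - 1)]
  m <- max(2L, ceiling(min_overlap * ns))
  best <- -Inf; best_lag <- NA_integer_
  for (lag in (-(ns - m)):(nl - m)) {
    i_s <- max(1L, 1L - lag); i_l <- max(1L, 1L + lag)
    len <- min(ns - i_s + 1L, nl - i_l + 1L)
    if (len < m) next
    va <- as.vector(win(short, i_s, len)); vb <- as.vector(win(long, i_l, len))
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    r <- stats::cor(va, vb)
    if (r > best) { best <- r; best_lag <- lag }
  }
  if (!is.finite(best)) {
    warning("undefined correlation: zero-variance input at every lag")
    return(NA_real_)
  }
  structure(best, lag = best_lag)
}

#' Acoustic similarity of every non-target word to the target
#'
#' For each non-target token: Pearson correlation and maximum
#' cross-correlation of the amplitude envelopes, the same two measures on
#' the cochleagrams, and the absolute duration difference to the target.
#'
#' @param tokens list of `token_audio` objects (non-targets).
#' @param target the target `token_audio`.
#' @param n_channels,f_range,frame_rate cochleagram settings.
#' @return data frame of class `similarity_scores`, one row per word.
#' @export
token_similarity <- function(tokens, target, n_channels = 32,
                             f_range = c(50, 8000), frame_rate = 100) {
  env_t <- extract_envelope(target)
  coch_t <- cochleagram(target, n_channels, f_range, frame_rate)
  rows <- lapply(tokens, function(tok) {
    env <- extract_envelope(tok)
    coch <- cochleagram(tok, n_channels, f_range, frame_rate)
    data.frame(word_id = tok$word_id,
               envelope_r = onset_corr(env, env_t),
               envelope_max_xcorr = as.numeric(max_xcorr(env, env_t)),
               cochleagram_r = onset_corr(coch, coch_t),
               cochleagram_max_xcorr = as.numeric(max_xcorr(coch, coch_t)),
               duration_diff = abs(tok$duration - target$duration))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_scores", "data.frame")
  out
}

#' Rank correlation of acoustic similarity with behavioral importance
#'
#' Spearman correlation (average ranks for ties) between each similarity
#' measure and the per-word permutation importance from the release-time
#' model, answering whether acoustically target-like words drive releases.
#'
#' @param scores a `similarity_scores` data frame.
#' @param importance data frame with `word_id` and `importance` columns
#'   (e.g. from [permutation_importance()] on the word-timing model, with
#'   `word_id` parsed from the feature names).
#' @return data frame with `measure`, `rho`, `p_value`, `n`.
#' @export
similarity_vs_importance <- function(scores, importance) {
  joined <- merge(scores, importance[c("word_id", "importance")],
                  by = "word_id")
  if (nrow(joined) < 5) stop("need at least 5 words with both scores")
  measures <- c("envelope_r", "envelope_max_xcorr", "cochleagram_r",
                "cochleagram_max_xcorr", "duration_diff")
  rows <- lapply(measures, function(m) {
    ct <- suppressWarnings(stats::cor.test(joined[[m]], joined$importance,
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(measure = m, rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(joined))
  })
  do.call(rbind, rows)
}
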