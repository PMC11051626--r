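test_that("word synthesis is deterministic and parameter-checked", {
  sp <- word_spec(3)
  a <- synth_word(sp, f0 = 191, sample_rate = 16000)
  b <- synth_word(sp, f0 = 191, sample_rate = 16000)
  expect_identical(a$samples, b$samples)
  expect_equal(max(abs(a$samples)), 1)
  expect_error(synth_word(sp, f0 = 191, duration = 0), "nonpositive")
  expect_error(synth_word(sp, f0 = 6000, sample_rate = 16000), "f0")
  # the template is a function of word_id only
  expect_identical(word_spec(3)$formants, sp$formants)
  expect_false(identical(word_spec(4)$formants, sp$formants))
})

test_that("envelope extraction tracks amplitude modulation", {
  sr <- 8000
  t <- seq_len(2 * sr) / sr
  # constant tone: flat envelope away from edges
  tone <- sin(2 * pi * 440 * t)
  env <- extract_envelope(tone, sample_rate = sr, env_rate = 500)
  mid <- env[100:(length(env) - 100)]
  expect_lt(stats::sd(mid) / mean(mid), 0.05)
  # 4 Hz AM tone: envelope spectrum peaks at 4 Hz
  am <- (1 + 0.9 * sin(2 * pi * 4 * t)) * sin(2 * pi * 440 * t)
  env_am <- extract_envelope(am, sample_rate = sr, env_rate = 500)
  sp <- Mod(stats::fft(env_am - mean(env_am)))[2:50]
  freqs <- (1:49) / (length(env_am) / 500)
  expect_equal(freqs[which.max(sp)], 4, tolerance = 0.3)
  # silence maps to (numerical) zero
  env0 <- extract_envelope(numeric(4000), sample_rate = sr)
  expect_lt(max(env0), 1e-10)
  expect_error(extract_envelope(numeric(4), sample_rate = sr),
               "short-signal")
})

test_that("the cochleagram behaves like a filterbank", {
  sr <- 16000
  t <- seq_len(round(0.4 * sr)) / sr
  cfs_probe <- c(500, 2000)
  for (f in cfs_probe) {
    tone <- sin(2 * pi * f * t)
    cg <- cochleagram(tone, n_channels = 24, f_range = c(100, 6000),
                      sample_rate = sr)
    cf <- attr(cg, "cf")
    expect_true(all(diff(cf) > 0))
    expect_true(all(cg >= 0))
    # the maximally driven channel is the one tuned to the tone
    best <- which.max(rowSums(cg))
    expect_equal(cf[best], f, tolerance = 0.15 * f)
  }
  # silence gives an all-zero (numerically) matrix
  cg0 <- cochleagram(numeric(4000), n_channels = 8, f_range = c(100, 6000),
                     sample_rate = sr)
  expect_lt(max(cg0), 1e-8)
  # amplitude scaling is monotone cell by cell
  tone <- sin(2 * pi * 800 * t)
  c1 <- cochleagram(tone, n_channels = 8, f_range = c(100, 6000),
                    sample_rate = sr)
  c2 <- cochleagram(2 * tone, n_channels = 8, f_range = c(100, 6000),
                    sample_rate = sr)
  expect_true(all(c2 - c1 >= -1e-9))
  expect_error(cochleagram(tone, n_channels = 1, sample_rate = sr),
               "configuration error")
  expect_error(cochleagram(tone, f_range = c(100, 9000), sample_rate = sr),
               "configuration error")
})

test_that("correlation measures satisfy their identities", {
  set.seed(8)
  a <- as.vector(stats::filter(rnorm(300), rep(0.2, 5), sides = 1))
  a[is.na(a)] <- 0
  # identical inputs: both measures are exactly 1
  expect_equal(onset_corr(a, a), 1)
  expect_equal(as.numeric(max_xcorr(a, a)), 1)
  # a time-shifted copy: max_xcorr recovers it at the compensating lag
  b <- c(numeric(40), a)
  mx <- max_xcorr(a, b)
  expect_equal(as.numeric(mx), 1, tolerance = 1e-6)
  expect_equal(attr(mx, "lag"), 40)
  expect_lt(onset_corr(a, b), 1)
  # orthogonal equal-length sinusoids with integer periods
  t <- seq_len(200)
  s1 <- sin(2 * pi * 5 * t / 200); s2 <- cos(2 * pi * 5 * t / 200)
  expect_equal(onset_corr(s1, s2), 0, tolerance = 1e-10)
  # max over lags includes lag zero for equal-length inputs
  set.seed(9)
  for (i in 1:5) {
    u <- rnorm(80); v <- rnorm(80)
    expect_gte(as.numeric(max_xcorr(u, v)) + 1e-12, onset_corr(u, v))
    # symmetry under argument swap
    expect_equal(as.numeric(max_xcorr(u, v)), as.numeric(max_xcorr(v, u)))
    expect_equal(onset_corr(u, v), onset_corr(v, u))
  }
  # zero variance is flagged, not silently correlated
  expect_warning(r0 <- onset_corr(rep(1, 50), rnorm(50)), "undefined")
  expect_true(is.na(r0))
})

test_that("cochleagram similarity is higher across F0 than across words", {
  sp0 <- word_spec(0)
  t_nat <- synth_word(sp0, f0 = 191, sample_rate = 12000)
  t_low <- synth_word(sp0, f0 = 144, sample_rate = 12000)
  other <- synth_word(word_spec(9), f0 = 191, sample_rate = 12000)
  cg <- function(a) cochleagram(a, n_channels = 24, f_range = c(100, 5000))
  r_f0 <- onset_corr(cg(t_nat), cg(t_low))
  r_word <- onset_corr(cg(t_nat), cg(other))
  expect_gt(r_f0, r_word)
})

test_that("similarity scores join importance and rank-correlate", {
  sp0 <- word_spec(0)
  target <- synth_word(sp0, f0 = 191, sample_rate = 12000)
  toks <- lapply(1:6, function(w) synth_word(word_spec(w), f0 = 191,
                                             sample_rate = 12000))
  sim <- token_similarity(toks, target, n_channels = 16,
                          f_range = c(100, 5000))
  expect_equal(nrow(sim), 6)
  expect_true(all(abs(sim$cochleagram_max_xcorr) <= 1))
  expect_true(all(sim$duration_diff >= 0))
  # perfectly monotone importance: rho = 1 for the tracked measure
  imp <- data.frame(word_id = sim$word_id,
                    importance = rank(sim$cochleagram_max_xcorr))
  sv <- similarity_vs_importance(sim, imp)
  expect_equal(sv$rho[sv$measure == "cochleagram_max_xcorr"], 1)
  expect_error(similarity_vs_importance(sim[1:3, ], imp), "at least 5")
})
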