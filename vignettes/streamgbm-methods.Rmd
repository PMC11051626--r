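---
title: "Models and methods behind streamgbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind streamgbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`streamgbm` analyzes single-trial behavior in an auditory Go/No-Go
word-stream task: an animal holds a centre port while a stream of spoken
word tokens plays, releases when the target word occurs, and withholds on
catch trials. The package provides the full analysis chain — signal
detection metrics, gradient-boosted trial-outcome and reaction-time models
with feature attribution, a per-word release-time attribution with a
frequency-flattening resampler, acoustic similarity scoring, and
mixed-model baselines — together with a parametric simulator so that every
stage can be validated by parameter recovery. This vignette explains the
models, the tunable parameters, and the numerical and design choices.

## The task and outcome schema

A trial is a sequence of word tokens with at least `min_gap` (default
0.08 s) of silence between them. Non-catch trials contain exactly one
target whose onset is uniform on 0.5–6.5 s; catch trials (25% by default)
contain none and are duration-matched. Outcomes follow the standard
Go/No-Go definitions: a release within the 2 s response window after
target onset is a *hit*; holding through the window is a *miss*; a release
before the target, or any release on a catch trial, is a *false alarm*;
holding through a catch trial is a *correct rejection*. We treat the
window as half-open — a release at exactly the target onset is still a
false alarm, since the decision cannot yet have used the target. Session
summaries report `p(hit) = hits/(hits+misses)`, `p(FA) = FA/total`,
`p(correct) = (hits+CR)/total` and `d' = z(p(hit)) − z(p(FA))`; rates of
exactly 0 or 1 are clipped to `1/(2N)` before the normal quantile (the
usual log-linear correction; the choice only matters for tiny sessions).
With a uniformly timed target, guessing yields
`response_window / trial_duration` correct — 1/3 for a 2 s window in a 6 s
trial — which is the reference point for above-chance performance.

## The simulated observer

The generator's defaults are the study conditions: 54 non-target words
sampled with replacement, talker-specific F0 triplets {109, 124, 144} Hz
(male) and {144, 191, 251} Hz (female), and three roving modes (control:
natural F0; inter: the whole trial shifted to the low or high F0; intra:
each token's F0 drawn independently from the triplet). Gaps are
`min_gap` plus a 0–40 ms uniform jitter; token durations are log-uniform
on 0.25–0.6 s, ordinary magnitudes for spoken words. An optional biased
subset of words occurs more frequently (multiplier 1.8 by default,
matching an 80% over-representation read multiplicatively).

The observer is a discrete per-token hazard model rather than a
continuous-time one: each pre-target token carries a release probability
`plogis(base + ferret + confusability(word) + intra-rove + talker +
time-in-trial terms)`, and the first sampled release produces a false
alarm at that token's onset plus a fixed latency (0.25 s). This mirrors
the empirical finding that releases are predictable from token timing. If
the target is reached, it is missed with log-odds
`qlogis(1 − detection) + talker + ferret terms` (plus a lapse), and
otherwise answered after
`rt_base + talker + F0 + precursor-mismatch + target-time terms +`
truncated Gaussian noise confined to the response window. The Gaussian
family is a modelling convenience; nothing downstream depends on it. All
effect parameters default to zero, so the default observer is a
well-trained unbiased animal (~90% detection, per-token hazard −4
log-odds giving false-alarm rates near 15%); studies inject effects
explicitly and then try to recover them.

What the generator does *not* emulate: attention drifts within sessions,
motor variability in the latency of false alarms, acoustic rendering of
the actual streams (token audio is synthesized separately, see below),
training-stage attenuation cues, or lateralization errors (the source
task's animals essentially never made them). Passing recovery tests
therefore shows the *analysis* is correct and sensitive at these effect
sizes, not that real ferret data will be as clean.

## Boosted models and their protocol

The four trial-level models mirror the study design: a miss/hit classifier
(target trials only), a false-alarm classifier (all trials), a
reaction-time regression (hits only), and per-talker release-time models
over word-onset columns. Classifiers train on binary log loss for up to
10,000 rounds, regressions on the l2 loss for up to 1,000 rounds, both
with early stopping after 100 stagnant rounds on a 20% stratified
validation split inside each training fold (the stopping holdout is our
choice; any inner split works). Metrics come from stratified 5-fold
cross-validation; balanced accuracy (mean of per-class recalls) is
reported alongside raw accuracy because misses and false alarms are rare.
Folds are trial-stratified rather than ferret-grouped, matching the
within-animal random-effect treatment of the baselines. Class and
rove-condition imbalance is handled by subsampling to the minimum level
count before the fold split; a sensitivity toggle is unnecessary because
the subsampler returns indices and can be applied anywhere. Training is
single-threaded and seeded, so every fit in the test suite is
bit-reproducible. Analyses in this repository run reduced protocols
(hundreds of rounds, stopping patience 25–40) — at a few thousand trials
the validation loss plateaus long before the full budgets.

The shuffled-label noise floor refits the model on permuted labels with
the hyperparameters held constant and records the held-out metric; we use
a fixed stratified 80/20 split per shuffle rather than full CV per
shuffle, which estimates the same mean floor at a fifth of the cost. For
data with real structure the floor sits above the fitted error in
essentially every shuffle; for pure noise the two distributions overlap,
and the floor's mean equals the label variance (the mean-predicting
null).

Hyperparameter search is a seeded grid over a declared space, scored by
cross-validated log loss or MSE. Published hyperparameter tables are
deliberately not hard-coded; the defaults (depth 3, learning rate 0.1,
L2 regularization 1) are ordinary starting points.

## Attribution: gain, permutation, SHAP

Cumulative gain importance sums each feature's split gain across all
trees; the "elbow" is formalized as the smallest prefix of features
reaching 95% of total gain (the threshold is configurable — "did not
significantly increase" is not operational as stated, so we also provide
the permutation-based null below as an alternative selection rule).

Permutation importance is implemented from first principles: shuffle one
column of held-out data, recompute the score, and report the mean drop
over repeats with its standard deviation (10 repeats by default). For a
cross-validated model the held-out data are the test folds scored by each
fold's own model. The known caveat that correlated features share credit
is reproduced, not patched: duplicating an informative feature roughly
halves each copy's permutation importance while their summed SHAP
attribution is conserved.

SHAP values use the path-dependent (cover-weighted) conditional
expectation game: features outside the conditioning set descend both
children of a split in proportion to training cover. `shap_attribution()`
computes *exact* Shapley values of this game in double precision from the
parsed trees — per tree, only the features that tree splits on can carry
credit (they are dummy players otherwise), so each tree's game is solved
by enumeration over its own used-feature subsets and summed across trees
by linearity. Observations are first collapsed to the tree's
split-decision patterns, which keeps the enumeration fast at depth 3. Two
independent checks guard this code: a brute-force oracle that enumerates
all `2^M` subsets of the whole model with standard Shapley weights
(agreement to ~1e-15), and the booster's own C++ TreeSHAP (agreement to
float32 precision, ~1e-5). Classifier attributions are in log-odds;
regression attributions in seconds.

A numerical subtlety worth recording: the booster stores thresholds, leaf
values and inputs as float32. All parsed values and all attribution inputs
are snapped to float32 before traversal, so split routing matches the
fitted model exactly, while the arithmetic on top stays double. Local
accuracy (contributions + expected value = raw margin) is then an exact
identity of our computation, and holds below 1e-10 on every observation of
every model in the test suite.

## Per-word attribution and the flattening resampler

The release-time models predict when the animal leaves the port using
only the onset of each word's first occurrence in the trial (one column
per word, target included). Absent words hold the native missing-value
sentinel, *not* zero — zero is a legal onset. Repeat occurrences (the
vocabulary is sampled with replacement) keep their count as a diagnostic.

Because sampled word frequencies need not be uniform, the resampler walks
the vocabulary forward then in reverse, subsampling the trials containing
each word to a fixed floor (designated high-frequency words to a smaller
cap, or skipped at cap 0) and concatenating, for a configurable number of
cycles. What this procedure equalizes is each word's *guaranteed
representation* — the number of resampled rows selected on its behalf —
and that is the quantity our uniformity diagnostic measures. It provably
does not equalize marginal token frequencies: with ~14 tokens per trial, a
5x over-represented word still appears in other words' selections roughly
in proportion to its frequency, and no trial-level subsampling scheme that
keeps whole trials can undo that. The robustness check that matters is
therefore the one the package tests: per-word importances from flattened
and natural-frequency inputs are strongly rank-correlated, so the
conclusions do not hinge on the resampling.

## Acoustic similarity

Synthetic word tokens are generated source–filter style: a harmonic
complex at the voice F0 shaped by 2–3 word-specific resonances under a
word-specific syllable envelope, deterministic given the word id. Changing
F0 moves the fine structure but not the spectrotemporal template, which is
exactly the invariance the task manipulates. The amplitude envelope is the
analytic-signal magnitude low-passed at 30 Hz (a common psychoacoustic
choice). The cochleagram is a 4th-order gammatone filterbank on an
ERB-spaced axis (64 channels, 50 Hz–8 kHz by default), half-wave
rectified, smoothed, cube-root compressed and framed at 100 Hz; these are
standard human-periphery defaults and likely overestimate the spectral
resolution of a ferret — a caveat we document rather than model. Two
similarity measures compare a word to the target: an onset-aligned Pearson
correlation after truncation to the common duration (matrices compared
cell by cell — the flattened-matrix convention; a per-channel mean changes
little and is not exposed), and the maximum normalized cross-correlation
over time lags with at least 50% overlap of the shorter token, which
allows any part of one word to resemble any part of the other. Similarity
is linked to behavior by the Spearman correlation between each measure and
the per-word permutation importance of the release-time model.

## Baselines

The mixed-model baselines consume the *identical* feature tables as the
boosters (integer codes decoded back to factors; reference levels: male
talker, left side, lowest F0). Outcome models are binomial GLMMs with a
logit link, reaction times a Gaussian LMM, both with a per-ferret random
intercept and the same 5-fold CV; held-out predictions use the estimated
intercepts of the seen groups (predicting with the population average
instead changes the metrics negligibly here — the toggle was not worth an
interface). p-values are Wald z (GLMM) and Satterthwaite t (LMM). The OLS
counterpart of the word model cannot consume missing values, so absent
words are imputed to a constant beyond any trial duration with per-word
absence indicators; rank-deficient columns are dropped with a warning.
On linear data OLS matches the booster; on the word-timing problem —
where the response is "release at the first sufficiently confusable
token", a rule not expressible as a linear function of onset columns with
imputation — the booster's CV error is roughly half the OLS error in this
repository's runs.

## Null calibration and a known leakage

With all injectable effects zeroed, the miss/hit model sits within
binomial noise of 0.5 balanced accuracy and no feature's permutation
importance exceeds twice its repeat SD. The false-alarm model is the
deliberate exception: its published covariate set includes the realized
trial-end time and trial duration, which mechanically encode whether the
trial terminated early under *any* release process. A null observer still
false-alarms at a constant hazard, so this model classifies well above
chance with zero injected effects — label leakage inherent to the
covariate definition, not a defect of the fitting code. The calibration
check for this model is therefore that its *stimulus and history*
features stay silent under the null, and users should read its timing
features descriptively, not causally.

## Problem sizes and determinism

The analysis scripts simulate 10,000 trials; the recovery tests use
8,000 (outcome/RT models), 6,000 (flattening comparison) and 8,000
(acoustic linkage), with 100 shuffles for the noise floor and reduced
boosting budgets as described above — sizes at which every injected
effect is comfortably detectable. Every stochastic step takes an explicit
seed, single-threaded training keeps fits bit-identical, and rerunning a
study configuration reproduces identical artifact hashes.

## Known limitations

Attenuation-cue trials (excluded from the source analyses) carry no model
here — the schema's exclusion flag is the extension point. The observer
has no within-session nonstationarity, so trial-number effects can only
be recovered if injected through the hazard slope. The acoustic stage
scores synthetic tokens; conclusions about real recordings require
supplying real WAV-derived waveforms to the same functions. And the exact
SHAP path assumes trees of modest depth (enumeration is exponential in a
tree's distinct split features); for depth far beyond the defaults,
delegate attribution to the booster's TreeSHAP and accept float32
precision.
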