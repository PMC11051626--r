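# streamgbm

Gradient-boosted analysis of auditory Go/No-Go word-stream behavior, with
a parametric simulator for end-to-end validation by parameter recovery.

## The problem

In word-stream psychophysics an animal (here modelled on ferrets) holds a
centre port while spoken word tokens play in sequence, releases when the
target word occurs, and withholds on catch trials. Sessions yield many
thousands of trials whose outcomes — hit, miss, false alarm, correct
rejection — depend on a tangle of stimulus factors (talker, fundamental
frequency F0, within-trial pitch roving), timing factors (target time,
trial number) and subject idiosyncrasies. Classical summaries
(p(hit), p(FA), d′ = z(p(hit)) − z(p(FA))) compress this to a few numbers;
mixed-effects models add per-trial covariates but struggle with
non-linear, interacting effects.

`streamgbm` implements the gradient-boosted alternative at production
quality, for behavioral scientists who want trial-level models *and*
attribution they can trust:

- **Trial schema** — outcome classification against a response window,
  session metrics, d′ with 0/1-rate clipping, chance level
  (`response_window / trial_duration`, e.g. 2 s / 6 s = 1/3).
- **Synthetic task + observer** — word streams (54-word vocabulary,
  targets uniform on 0.5–6.5 s, ≥0.08 s token gaps, 25% catch trials,
  inter/intra F0 roving over {109, 124, 144} Hz and {144, 191, 251} Hz)
  and a per-token release-hazard observer with injectable effect sizes,
  so every downstream stage is tested by recovering known ground truth.
- **Boosted models** — miss/hit and false-alarm classifiers (binary log
  loss, early stopping, balanced-class subsampling), reaction-time and
  per-word release-time regressions (l2 loss), all with stratified 5-fold
  CV, balanced accuracy, shuffled-label noise floors and seeded
  bit-reproducible training (via xgboost).
- **Attribution** — cumulative gain curves with elbow selection,
  permutation importance implemented from scratch, and *exact*
  double-precision Shapley values (path-dependent, cover-weighted) with a
  brute-force subset-enumeration oracle in the tests. Local accuracy
  (SHAP row sums + expected value = raw margin) is an identity, not an
  approximation.
- **Word attribution** — release-time prediction from word-onset columns
  with NA sentinels, plus the forward/reverse frequency-flattening
  resampler for non-uniform word corpora.
- **Acoustics** — synthetic word tokens (harmonic source, formant filter,
  syllable envelope), Hilbert-envelope extraction, ERB-spaced gammatone
  cochleagrams, onset-aligned correlation and maximum cross-correlation,
  and Spearman linkage of acoustic similarity to behavioral importance.
- **Baselines** — binomial GLMM / Gaussian LMM with per-ferret random
  intercepts (lme4/lmerTest) and OLS on the word-timing matrix, consuming
  byte-identical feature tables for fair comparison.

## Worked example

```r
library(streamgbm)

# simulate 4,000 trials from an observer that misses the male talker more
# (+1 log-odds) and slows by 80 ms when the word before the target changes F0
study <- generate_study(
  session_config(n_trials = 4000),
  observer_params(miss_talker_effect = 1, rt_precursor_mismatch_effect = 0.08),
  seed = 1)
session_metrics(study$trials$outcome)
#> Go/No-Go session: 4000 trials (2159 hit, 484 miss, 516 FA, 841 CR)
#>   p(hit) = 0.817  p(FA) = 0.129  p(correct) = 0.750  d' = 2.03

# miss/hit classifier on a balanced subsample, 5-fold CV
ft <- build_features(study, feature_spec("miss_hit"))
idx <- subsample_balance(ft$y, seed = 1)
ft$x <- ft$x[idx, ]; ft$y <- ft$y[idx]
ft$groups <- ft$groups[idx]; ft$trial_id <- ft$trial_id[idx]
fit <- crossval_fit(ft, train_protocol("binary", max_epochs = 300,
                                       early_stopping_rounds = 30, seed = 1))
fit
#> gbm_report (miss_hit, binary): 968 rows, 9 features, 5 folds
#>   mean test accuracy 0.5826, balanced accuracy 0.5826

head(permutation_importance(fit, n_repeats = 5, seed = 1), 3)
#>            feature importance         sd n_repeats
#> 1           talker 0.07887027 0.04165252         5
#> 6        target_f0 0.01054983 0.01305890         5
#> 8 prev_was_correct 0.01054338 0.01276678         5

sh <- shap_attribution(fit)       # exact Shapley values, log-odds units
sh
#> shap_result: 968 observations x 9 features (log-odds), E[f] = -0.0001
#>   mean |SHAP|: talker=0.275, target_time=0.094, target_f0=0.085, ...
max(abs(rowSums(sh$values) + sh$expected_value - sh$margin))
#> [1] 0
```

Reading the output: the simulated animal performs like a trained subject
(d′ ≈ 2, 75% correct against a 33% chance level). The balanced accuracy of
0.58 on held-out folds shows misses are partly predictable, and both
permutation importance (a 0.079 accuracy drop when the talker column is
shuffled) and the mean |SHAP| of 0.275 log-odds identify the talker as the
dominant factor — the effect that was injected. The zero on the last line
is the local-accuracy identity of the exact Shapley computation.

## The analysis workflow

The `analysis/` scripts run the five-model study on a fully synthetic
dataset whose word confusions are driven by cochleagram similarity, and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # task + observer, behavior summary
Rscript analysis/02_outcome_models.R      # miss/hit + FA models, attribution
Rscript analysis/03_reaction_time.R       # RT regression, noise floor, LMM
Rscript analysis/04_word_attribution.R    # per-word release-time models + OLS
Rscript analysis/05_acoustic_similarity.R # similarity vs importance linkage
Rscript analysis/06_mixed_model_baselines.R
```

On the shipped configuration these recover every injected effect: talker
tops the miss model, intra-trial roving carries a positive false-alarm
SHAP contrast, the precursor-F0 mismatch appears as a +0.09 s SHAP
contrast and a −0.095 s (p ≈ 1e-50) LMM coefficient, the target word ranks
first in the release-time models with the booster's CV error less than
half the OLS error, and the cochleagram max-cross-correlation is the
strongest acoustic predictor of per-word importance
(ρ = 0.48, p = 3e-4), as designed.

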