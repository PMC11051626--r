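#!/usr/bin/env Rscript
# Stage 5: link per-word behavioral importance to acoustic similarity.
#
# The simulation made word confusability proportional to cochleagram
# similarity with the target (stage 1), so the Spearman correlation between
# per-word permutation importance (stage 4) and the cochleagram
# max-cross-correlation should come back significantly positive, and the
# envelope/duration measures should be weaker.

suppressMessages(library(streamgbm))
sim <- read.csv("results/similarity.csv")
pi_w <- read.csv("results/words_female_permutation.csv")

link <- similarity_vs_importance(sim, pi_w[pi_w$word_id > 0, ])
write.csv(link, "results/similarity_vs_importance.csv", row.names = FALSE)
print(link, digits = 3, row.names = FALSE)

best <- link[which.max(link$rho), ]
message(sprintf("strongest acoustic predictor: %s (rho = %.3f, p = %.2g, explaining ~%d%% of rank variance)",
                best$measure, best$rho, best$p_value,
                round(100 * best$rho^2)))
top <- pi_w$word_id[pi_w$word_id > 0][1]
message(sprintf("most release-driving word: word_%d (cochleagram similarity rank %d of %d)",
                top, match(top, sim$word_id[order(-sim$cochleagram_max_xcorr)]),
                nrow(sim)))
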