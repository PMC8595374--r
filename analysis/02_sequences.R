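#!/usr/bin/env Rscript
# Stage 2: cumulative-diagnosis state sequences.
#
# Converts each case's first-diagnosis events into a yearly sequence of
# cumulative diagnosis sets on the age grid (interval t holds the set of
# categories diagnosed strictly before age t), and exports them.

library(trajmorbid)

cohort <- read_cohort("results/data/cohort")
alphabet <- build_alphabet(default_categories())
cat("alphabet:", length(alphabet$states), "states over",
    alphabet$n_categories, "categories\n")

seqset <- build_sequences(cohort, alphabet, increment = 1,
                          target_length = 36L)
print(seqset)

l_obs <- vapply(seqset$sequences, `[[`, integer(1), "l_obs")
cat("observed lengths: median", stats::median(l_obs),
    "range", min(l_obs), "-", max(l_obs), "\n")

write_sequences(seqset, "results/sequences.csv")
cat("wrote results/sequences.csv\n")
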