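#!/usr/bin/env Rscript
# Stage 1: simulate the working cohort.
#
# Generates a registry-like birth cohort (births 1981-2002, follow-up to
# end of 2016) of schizophrenia cases drawn from five latent trajectory
# classes -- childhood-disorder, adult-multimorbidity, mood-only,
# substance, and low-comorbidity profiles -- plus two age/sex-matched
# controls per case, and writes it under results/data/cohort/.

library(trajmorbid)

n_cases <- 300L
seed <- 20260923L

cfg <- sim_config(n_cases = n_cases, n_controls_per_case = 2, seed = seed)
cohort <- simulate_cohort(cfg)
print(cohort)

cat("cases by latent class:\n")
print(table(cohort$truth$latent_class))

cat("censoring reasons:\n")
print(table(cohort$persons$censor_reason))

write_cohort(cohort, "results/data/cohort")
cat("wrote results/data/cohort/{persons,events,covariates,truth}.csv\n")
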