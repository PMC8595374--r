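#!/usr/bin/env Rscript
# Stage 6: risk-factor and outcome associations, plus replication.
#
# MANCOVA joint tests of each covariate against the three MDS dimension
# scores (adjusting for age at censoring and sex), post-hoc per-dimension
# regressions for the Bonferroni-significant ones, multinomial-logit
# cluster associations, and a replication run in which an independently
# simulated cohort is projected onto the primary MDS dimensions.

library(trajmorbid)

cohort <- read_cohort("results/data/cohort")
scores <- as.matrix(utils::read.csv("results/scores.csv",
                                    row.names = 1))
labels_df <- utils::read.csv("results/clusters.csv")

ids <- rownames(scores)
p <- cohort$persons[match(ids, cohort$persons$person_id), ]
cv <- cohort$covariates[match(ids, cohort$covariates$person_id), ]
covs <- data.frame(
  age_at_censoring = as.numeric(p$censor_date - p$birth_date) / 365.25,
  sex = as.integer(p$sex == "M"))

# outcomes are analyzed as average yearly admissions / days after onset
post_years <- pmax(as.numeric(p$censor_date - p$scz_first_date) / 365.25,
                   0.5)
vars <- data.frame(maternal_age = cv$maternal_age,
                   pgs_edu = cv$pgs_edu,
                   infection = cv$infection,
                   yearly_hospitalizations = cv$n_hospitalizations / post_years,
                   yearly_days_hospitalized = cv$days_hospitalized / post_years)

threshold <- as.numeric(bonferroni(0.05, ncol(vars)))
tab <- association_scan(scores, vars, covs, threshold = threshold)
cat(sprintf("joint MANCOVA tests, Bonferroni P < %.3g:\n", threshold))
print(transform(tab, F = round(F, 1), p = signif(p, 2)))
utils::write.table(tab, "results/associations.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

labels <- labels_df$cluster[match(ids, labels_df$person_id)]
for (v in names(vars)[which(tab$significant)]) {
  ca <- tryCatch(cluster_association(labels, vars[[v]], covs),
                 warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(ca)) {
    cat("\ncluster odds ratios for", v, "(reference = largest cluster):\n")
    print(transform(ca, or = round(or, 2), p = signif(p, 2)))
  }
}

# replication: an independent draw from the same generative model,
# projected onto the primary MDS dimensions
rep_cohort <- simulate_cohort(sim_config(n_cases = 150, seed = 424242L))
rep_seq <- build_sequences(rep_cohort)
prim_seq <- build_sequences(cohort)
rp <- rep_cohort$persons[match(vapply(rep_seq$sequences, `[[`,
                                      character(1), "person_id"),
                               rep_cohort$persons$person_id), ]
rcv <- rep_cohort$covariates[match(rp$person_id,
                                   rep_cohort$covariates$person_id), ]
rep_post <- pmax(as.numeric(rp$censor_date - rp$scz_first_date) / 365.25,
                 0.5)
rep_vars <- data.frame(maternal_age = rcv$maternal_age,
                       pgs_edu = rcv$pgs_edu,
                       infection = rcv$infection,
                       yearly_hospitalizations =
                         rcv$n_hospitalizations / rep_post,
                       yearly_days_hospitalized =
                         rcv$days_hospitalized / rep_post)
rep_covs <- data.frame(
  age_at_censoring = as.numeric(rp$censor_date - rp$birth_date) / 365.25,
  sex = as.integer(rp$sex == "M"))

rh <- replication_harness(prim_seq, rep_seq, vars, rep_vars,
                          covs, rep_covs, threshold = threshold)
cat(sprintf("\nreplication: %d significant coefficient signs compared, %s concordant\n",
            rh$n_compared,
            if (is.na(rh$concordance)) "none" else
              sprintf("%.0f%%", 100 * rh$concordance)))
utils::write.table(rh$replication, "results/replication_associations.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/{associations,replication_associations}.tsv\n")
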