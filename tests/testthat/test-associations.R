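set.seed(300)
n_ <- 300
scores_ <- matrix(rnorm(n_ * 3), n_, 3,
                  dimnames = list(NULL, paste0("dim", 1:3)))
covs_ <- data.frame(age = runif(n_, 16, 36), sex = rbinom(n_, 1, 0.5))

test_that("MANCOVA detects perfect association and rejects bad designs", {
  res <- mancova(scores_, scores_[, 1], covs_)
  expect_lt(res$joint_p, 1e-20)
  expect_equal(res$n_nonmissing, n_)
  expect_error(mancova(scores_, rep(1, n_)), "constant|collinear")
  expect_error(mancova(scores_, factor(sample(letters[1:3], n_, TRUE))),
               "one degree of freedom")
  # collinear covariates are named
  bad <- cbind(covs_, age2 = covs_$age * 2)
  expect_error(mancova(scores_, scores_[, 1], bad), "age2|collinear")
  # listwise deletion reports the analyzed n
  x <- scores_[, 1]; x[1:25] <- NA
  expect_equal(mancova(scores_, x, covs_)$n_nonmissing, n_ - 25)
})

test_that("MANCOVA agrees with the reference Pillai computation", {
  x <- rnorm(n_)
  res <- mancova(scores_, x, covs_)
  fit <- stats::manova(scores_ ~ age + sex + x,
                       data = cbind(covs_, x = x))
  ref <- summary(fit, test = "Pillai")$stats
  expect_equal(res$pillai, ref["x", "Pillai"], tolerance = 1e-10)
  expect_equal(res$joint_F, ref["x", "approx F"], tolerance = 1e-10)
  expect_equal(res$joint_p, ref["x", "Pr(>F)"], tolerance = 1e-10)
})

test_that("post-hoc regressions recover the inverse-regression limit", {
  set.seed(301)
  z <- matrix(rnorm(2000 * 3), 2000, 3)
  x <- 2 * z[, 1] + rnorm(2000, sd = 1e-4)
  ph <- posthoc_regressions(z, x, force = TRUE)
  expect_equal(ph$beta[1], 0.5, tolerance = 1e-3)
  expect_equal(ph$beta[2], 0, tolerance = 5e-2)
  expect_equal(ph$beta[3], 0, tolerance = 5e-2)
  expect_lt(ph$p[1], 1e-20)
  # gate on the joint test unless forced
  expect_error(posthoc_regressions(z, x, joint_p = 0.5), "did not pass")
  # missing values shrink the analyzed n
  x[1:10] <- NA
  expect_silent(posthoc_regressions(z, x, force = TRUE))
})

test_that("null post-hoc p-values are uniform", {
  set.seed(302)
  p <- replicate(400, {
    z <- matrix(rnorm(60 * 2), 60, 2)
    posthoc_regressions(z, rnorm(60), force = TRUE)$p[1]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("cluster association reduces to the 2x2 odds ratio", {
  set.seed(303)
  lab <- rep(c(1, 2), c(120, 80))
  x <- rbinom(200, 1, ifelse(lab == 1, 0.3, 0.6))
  res <- cluster_association(lab, x, reference = "1")
  tab <- table(x, lab)
  or_ref <- (tab["1", "2"] * tab["0", "1"]) / (tab["0", "2"] * tab["1", "1"])
  expect_equal(res$or[res$cluster == "2"], or_ref, tolerance = 1e-3)
  # a perfectly separating predictor raises the separation flag
  xs <- as.numeric(lab == 2)
  expect_warning(res_sep <- cluster_association(lab, xs, reference = "1"),
                 "separation")
  expect_true(any(res_sep$separation))
  expect_error(cluster_association(rep(1, 10), rnorm(10)), "two clusters")
})

test_that("association_scan mirrors the joint-then-post-hoc table", {
  set.seed(304)
  vars <- data.frame(hit = scores_[, 1] + rnorm(n_, sd = 0.3),
                     null = rnorm(n_))
  tab <- association_scan(scores_, vars, covs_, threshold = 0.002)
  expect_true(tab$significant[tab$variable == "hit"])
  expect_false(is.na(tab$beta1[tab$variable == "hit"]))
  expect_true(is.na(tab$beta1[tab$variable == "null"]))
})

test_that("a replication cohort identical to the primary reproduces it", {
  # fully observed sequences (every l_obs reaches the target), where the
  # optimal-matching self-distance is exactly zero and projection of a
  # duplicated sequence is exact; with imputed tails the expected-cost
  # self-distance is positive and the identity is only approximate
  co <- simulate_cohort(separable_sim_config(n_cases = 60, seed = 41,
                                             death_hazard = 0,
                                             emigration_hazard = 0))
  ss <- build_sequences(co, target_length = 14L)
  cv <- co$covariates[match(vapply(ss$sequences, `[[`, character(1),
                                   "person_id"),
                            co$covariates$person_id), ]
  vars <- data.frame(pgs = cv$pgs_edu, hosp = cv$n_hospitalizations)
  rh <- replication_harness(ss, ss, vars, vars, threshold = 0.05)
  expect_equal(unname(rh$replication_scores),
               unname(rh$embedding$scores), tolerance = 1e-6)
  expect_equal(rh$replication$p, rh$primary$p, tolerance = 1e-6)
  if (rh$n_compared > 0) expect_equal(rh$concordance, 1)
  expect_error(replication_harness(ss, make_seqset(list()), vars, vars),
               "empty replication")
})

test_that("planted covariate shifts replicate with concordant signs", {
  co1 <- simulate_cohort(separable_sim_config(n_cases = 80, seed = 43))
  co2 <- simulate_cohort(separable_sim_config(n_cases = 60, seed = 44))
  mk <- function(co, ss) {
    ids <- vapply(ss$sequences, `[[`, character(1), "person_id")
    cv <- co$covariates[match(ids, co$covariates$person_id), ]
    tr <- co$truth$latent_class[match(ids, co$truth$person_id)]
    # a covariate shifted in one latent class, so it associates with the
    # trajectory dimensions
    data.frame(shifted = cv$pgs_edu + 2 * (tr == "class1"),
               null = rnorm(nrow(cv)))
  }
  ss1 <- build_sequences(co1); ss2 <- build_sequences(co2)
  set.seed(45)
  rh <- replication_harness(ss1, ss2, mk(co1, ss1), mk(co2, ss2),
                            threshold = 0.002)
  expect_true(rh$primary$significant[1])
  expect_gte(rh$concordance, 0.9)
})
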