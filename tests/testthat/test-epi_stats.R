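test_that("relative risks reproduce the published register contrasts", {
  # substance abuse row: 2121/5432 cases vs 227/10864 controls
  rr <- relative_risk(2121, 5432, 227, 10864)
  expect_equal(round(rr$rr, 1), 18.7)
  expect_equal(round(rr$ci_low, 1), 16.4)
  expect_equal(round(rr$ci_high, 1), 21.3)
  # eating disorders: 370 vs 120
  rr2 <- relative_risk(370, 5432, 120, 10864)
  expect_equal(round(rr2$rr, 1), 6.2)
  expect_equal(round(rr2$ci_low, 1), 5.0)
  expect_equal(round(rr2$ci_high, 1), 7.6)
  # any comorbidity: 4456 vs 1277
  rr3 <- relative_risk(4456, 5432, 1277, 10864)
  expect_equal(round(rr3$rr, 1), 7.0)
  # degenerate all-events table
  rr4 <- relative_risk(100, 100, 200, 200)
  expect_equal(rr4$rr, 1)
  expect_equal(rr4$ci_low, 1)
  expect_equal(rr4$ci_high, 1)
  expect_error(relative_risk(0, 10, 5, 10), "zero event cell")
  # invariance to scaling both arms
  rr5 <- relative_risk(37, 543, 12, 1086)
  rr6 <- relative_risk(370, 5430, 120, 10860)
  expect_equal(rr5$rr, rr6$rr)
})

test_that("Bonferroni thresholds display at two significant digits", {
  t25 <- bonferroni(0.05, 25)
  expect_equal(as.numeric(t25), 0.002)
  expect_equal(attr(t25, "display"), 0.002)
  t56 <- bonferroni(0.05, 56)
  expect_equal(as.numeric(t56), 0.05 / 56)
  expect_equal(attr(t56, "display"), 0.00089)
  expect_equal(as.numeric(bonferroni(0.05, 1)), 0.05)
  expect_error(bonferroni(0.05, 0), "at least 1")
})

test_that("Kaplan-Meier incidence reduces to the ECDF without censoring", {
  cats <- "F1"
  n <- 40
  birth <- as.Date("1981-06-01")
  ev_ages <- seq(1, 20, length.out = n)  # everyone diagnosed, no censoring
  persons <- data.frame(
    person_id = sprintf("P%02d", 1:n), sex = "F",
    birth_date = birth,
    censor_date = birth + round(36 * 365.25),
    censor_reason = "end_of_followup",
    scz_first_date = birth + round(15 * 365.25),
    group = "case", stringsAsFactors = FALSE)
  events <- data.frame(person_id = persons$person_id, category = "F1",
                       first_date = birth + round(ev_ages * 365.25),
                       stringsAsFactors = FALSE)
  co <- structure(list(persons = persons, events = events,
                       covariates = NULL, truth = NULL, categories = cats),
                  class = "cohort")
  ci <- cumulative_incidence(co, "F1", at_age = 10)
  expect_equal(ci$estimate, mean(ev_ages <= 10), tolerance = 1e-6)
  # monotone in age, within [0, 1]
  ests <- vapply(c(2, 5, 10, 15, 20), function(a)
    cumulative_incidence(co, "F1", a)$estimate, numeric(1))
  expect_true(all(diff(ests) >= 0))
  expect_true(all(ests >= 0 & ests <= 1))
  # before/after decomposition apportions by observed event ordering
  ci_split <- cumulative_incidence(co, "F1", 20, split_by_index = TRUE)
  expect_equal(ci_split$before_fraction, mean(ev_ages <= 15), tolerance = 1e-6)
  expect_equal(ci_split$before + ci_split$after, ci_split$estimate)
  # all persons censored before the requested age
  co2 <- co
  co2$persons$censor_date <- birth + 365
  co2$events <- co2$events[0, ]
  expect_error(cumulative_incidence(co2, "F1", 10), "under observation")
})

test_that("simulated constant-hazard incidence matches the closed form", {
  cfg <- sim_config(n_cases = 5000, n_controls_per_case = 0,
                    birth_window = c(1981L, 1981L),
                    categories = "F1",
                    latent_classes = list(class_spec(1, c(F1 = 0.05))),
                    death_hazard = 0, emigration_hazard = 0,
                    covariates = list(), seed = 33)
  co <- simulate_cohort(cfg)
  ci <- cumulative_incidence(co, "F1", 30)
  p_true <- 1 - 0.95^30
  se <- sqrt(p_true * (1 - p_true) / 5000)
  expect_lt(abs(ci$estimate - p_true), 3 * se)
})

test_that("episode splitting preserves person-time exactly", {
  split1 <- trajmorbid:::episode_split_pair(t_event = 20, status = 1,
                                            t_exposure = 7.25)
  expect_equal(nrow(split1), 2L)
  expect_equal(sum(split1$tstop - split1$tstart), 20)
  expect_equal(split1$status, c(0L, 1L))
  expect_equal(split1$prior, c(0L, 1L))
  # exposure after the event: single unexposed episode
  split2 <- trajmorbid:::episode_split_pair(20, 1, 25)
  expect_equal(nrow(split2), 1L)
  expect_equal(split2$prior, 0L)
  split3 <- trajmorbid:::episode_split_pair(20, 0, NA)
  expect_equal(sum(split3$tstop - split3$tstart), 20)
})

test_that("pairwise hazards cover all ordered pairs with Bonferroni control", {
  co <- simulate_cohort(sim_config(n_cases = 150, seed = 23))
  hz <- pairwise_hazards(co)
  expect_equal(nrow(hz), 56L)  # 8 * 7 ordered pairs
  expect_equal(attr(hz, "n_tests"), 56L)
  expect_equal(signif(attr(hz, "bonferroni_threshold"), 2), 0.00089)
  # pairs without exposed events are flagged, not reported as estimates
  expect_true(all(is.na(hz$hr[hz$flagged])))
  expect_true(all(is.finite(hz$hr[!hz$flagged])))
  expect_true(all(hz$wald_p[!hz$flagged] >= 0 & hz$wald_p[!hz$flagged] <= 1))
})

test_that("a planted hazard multiplier is recovered by the Cox stage", {
  cats <- c("A", "B")
  mult <- matrix(1, 2, 2, dimnames = list(cats, cats))
  mult["A", "B"] <- 3
  cfg <- sim_config(
    n_cases = 1500, n_controls_per_case = 0,
    categories = cats,
    latent_classes = list(class_spec(1, c(A = 0.05, B = 0.02), mult)),
    death_hazard = 0, emigration_hazard = 0,
    covariates = list(), seed = 55)
  co <- simulate_cohort(cfg)
  hz <- pairwise_hazards(co, categories = cats)
  ab <- hz[hz$first == "A" & hz$second == "B", ]
  expect_false(ab$flagged)
  expect_gt(ab$ci_high, 3 * 0.95)
  expect_lt(ab$ci_low, 3 * 1.05)
  expect_equal(ab$hr, 3, tolerance = 0.25)
  # the reverse direction stays near 1
  ba <- hz[hz$first == "B" & hz$second == "A", ]
  expect_equal(ba$hr, 1, tolerance = 0.35)
})
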