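test_that("zero hazards yield an event-free, administratively censored cohort", {
  cats <- default_categories()
  h0 <- stats::setNames(rep(0, length(cats)), cats)
  cfg <- sim_config(n_cases = 30,
                    latent_classes = list(class_spec(1, h0)),
                    control_class = class_spec(1, h0),
                    death_hazard = 0, emigration_hazard = 0,
                    seed = 7)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$events), 0L)
  expect_true(all(co$persons$censor_reason == "end_of_followup"))
  expect_true(all(co$persons$censor_date == cfg$followup_end))
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_config(n_cases = 40, seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # an explicit seed argument overrides and is reproducible too
  expect_identical(simulate_cohort(cfg, seed = 5),
                   simulate_cohort(cfg, seed = 5))
})

test_that("invalid hazards are rejected at configuration time", {
  cats <- default_categories()
  h <- stats::setNames(rep(0.01, length(cats)), cats)
  expect_error(class_spec(1, replace(h, 1, -0.1)), "in \\[0, 1\\]")
  expect_error(sim_config(death_hazard = 1.5), "probabilities")
  expect_error(sim_config(birth_window = c(2000L, 1990L)), "empty")
  bad <- default_latent_classes()
  bad[[1]]$weight <- 0.9
  expect_error(sim_config(latent_classes = bad), "sum to 1")
})

test_that("diagnosis accrual is monotone and events respect the window", {
  co <- simulate_cohort(sim_config(n_cases = 80, seed = 2))
  # at most one first diagnosis per category per person
  expect_false(any(duplicated(co$events[, c("person_id", "category")])))
  idx <- match(co$events$person_id, co$persons$person_id)
  expect_true(all(co$events$first_date >= co$persons$birth_date[idx]))
  expect_true(all(co$events$first_date <= co$persons$censor_date[idx]))
  # cases carry an index diagnosis, controls never do
  is_case <- co$persons$group == "case"
  expect_true(all(!is.na(co$persons$scz_first_date[is_case])))
  expect_true(all(is.na(co$persons$scz_first_date[!is_case])))
  # controls duplicate case birth dates and sexes (age/sex matching)
  n_case <- sum(is_case)
  expect_identical(co$persons$birth_date[!is_case],
                   rep(co$persons$birth_date[is_case], 2))
  expect_identical(co$persons$sex[!is_case],
                   rep(co$persons$sex[is_case], 2))
})

test_that("constant-hazard incidence matches the geometric closed form", {
  # one class, one category, h = 0.05/yr, 35y follow-up, no censoring
  cfg <- sim_config(n_cases = 5000, n_controls_per_case = 0,
                    birth_window = c(1981L, 1981L),
                    followup_end = as.Date("2016-12-31"),
                    categories = "F1",
                    latent_classes = list(
                      class_spec(1, c(F1 = 0.05),
                                 scz_onset = list(mean = 20, sd = 4,
                                                  min = 10, max = 30))),
                    control_class = class_spec(1, c(F1 = 0)),
                    death_hazard = 0, emigration_hazard = 0,
                    covariates = list(),
                    seed = 42)
  co <- simulate_cohort(cfg)
  age <- as.numeric(co$events$first_date -
                      co$persons$birth_date[match(co$events$person_id,
                                                  co$persons$person_id)]) /
    365.25
  p_hat <- sum(age <= 35) / nrow(co$persons)
  p_true <- 1 - (1 - 0.05)^35
  se <- sqrt(p_true * (1 - p_true) / nrow(co$persons))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("cohorts round-trip through the CSV files", {
  co <- simulate_cohort(sim_config(n_cases = 50, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$persons, co$persons)
  expect_equal(back$events, co$events)
  expect_equal(back$covariates, co$covariates)
  expect_equal(back$truth, co$truth)
})

test_that("an empty cohort writes header-only files", {
  cats <- default_categories()
  h0 <- stats::setNames(rep(0, length(cats)), cats)
  cfg <- sim_config(n_cases = 1, n_controls_per_case = 0,
                    latent_classes = list(class_spec(1, h0)),
                    death_hazard = 0, emigration_hazard = 0, seed = 1)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_length(readLines(file.path(dir, "events.csv")), 1L)
})

test_that("malformed or invariant-violating files are rejected with line info", {
  co <- simulate_cohort(sim_config(n_cases = 10, seed = 4))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  # event before birth
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        colClasses = "character")
  if (nrow(ev) == 0) skip("no events drawn")
  ev$first_date[1] <- "1900-01-01"
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "data line 1.*outside")
  ev$first_date[1] <- "not-a-date"
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "data line 1.*ISO-8601")
})
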