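#' Specify a latent trajectory class for the synthetic registry
#'
#' The generator draws each case from a mixture of latent classes. A class
#' fixes the yearly first-diagnosis hazards of the comorbidity categories,
#' how a prior diagnosis in one category multiplies the hazard of later
#' diagnoses in another, the age-at-onset distribution of the index
#' (schizophrenia) diagnosis, mean shifts planted on covariates, and the
#' expected yearly number of psychiatric hospitalizations after onset.
#'
#' @param weight mixture weight in `[0, 1]`
#' @param base_hazard named numeric vector of per-year first-diagnosis
#'   probabilities, one per category
#' @param pair_multipliers square numeric matrix (rows = prior category,
#'   columns = later category) of hazard multipliers applied from the date
#'   of the prior diagnosis onwards; defaults to all 1 (no interaction).
#'   Multipliers act on the hazard-rate scale, so a multiplier of `m` is
#'   the hazard ratio a time-dependent Cox model estimates.
#' @param scz_onset list with `mean`, `sd`, `min`, `max`: a truncated
#'   normal age-at-onset (years) for the index diagnosis
#' @param covariate_shifts named numeric vector: additive mean shift for
#'   continuous covariates, additive log-odds shift for binary ones
#' @param hospitalization_mean expected yearly admissions after onset
#' @return an object of class `class_spec`
#' @export
class_spec <- function(weight,
                       base_hazard,
                       pair_multipliers = NULL,
                       scz_onset = list(mean = 22, sd = 5, min = 10, max = 35),
                       covariate_shifts = numeric(0),
                       hospitalization_mean = 0.5) {
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0, weight <= 1)
  if (any(base_hazard < 0) || any(base_hazard > 1))
    stop("base hazards must be yearly probabilities in [0, 1]")
  C <- length(base_hazard)
  if (is.null(pair_multipliers))
    pair_multipliers <- matrix(1, C, C,
                               dimnames = list(names(base_hazard), names(base_hazard)))
  pair_multipliers <- as.matrix(pair_multipliers)
  if (!all(dim(pair_multipliers) == C))
    stop("pair_multipliers must be ", C, "x", C)
  if (any(pair_multipliers < 0)) stop("pair multipliers must be nonnegative")
  structure(list(weight = weight,
                 base_hazard = base_hazard,
                 pair_multipliers = pair_multipliers,
                 scz_onset = scz_onset,
                 covariate_shifts = covariate_shifts,
                 hospitalization_mean = hospitalization_mean),
            class = "class_spec")
}

#' Default latent classes emulating five clinical trajectory profiles
#'
#' Five classes mirror the trajectory subgroups commonly described in
#' schizophrenia cohorts: comorbid childhood disorders; multiple adult
#' comorbidities; mood-disorder-only; comorbid substance abuse; and little
#' comorbidity. Mixture weights are proportional to the subgroup sizes
#' reported for Danish register cohorts (roughly 11/29/13/13/33 percent).
#'
#' @param categories category labels (default [default_categories()])
#' @return list of [class_spec()] objects whose weights sum to 1
#' @export
default_latent_classes <- function(categories = default_categories()) {
  C <- length(categories)
  base <- function(...) {
    h <- stats::setNames(rep(0.002, C), categories)
    shift <- c(...)
    h[names(shift)] <- shift
    h
  }
  w <- c(597, 1580, 734, 729, 1792)
  w <- w / sum(w)
  childhood <- class_spec(
    w[1],
    base(F70 = 0.02, F84 = 0.03, F9 = 0.06, F1 = 0.008, F60 = 0.006),
    scz_onset = list(mean = 19, sd = 4, min = 10, max = 35),
    covariate_shifts = c(pgs_edu = -0.3, infection = 0.4),
    hospitalization_mean = 0.6)
  adult <- class_spec(
    w[2],
    base(F1 = 0.025, F3 = 0.04, F4 = 0.025, F50 = 0.008, F60 = 0.035),
    scz_onset = list(mean = 23, sd = 5, min = 12, max = 35),
    covariate_shifts = c(maternal_age = -1.0, infection = 0.5),
    hospitalization_mean = 1.0)
  mood <- class_spec(
    w[3],
    base(F3 = 0.045),
    scz_onset = list(mean = 24, sd = 5, min = 12, max = 35),
    covariate_shifts = c(maternal_age = 0.5),
    hospitalization_mean = 0.4)
  substance <- class_spec(
    w[4],
    base(F1 = 0.06, F60 = 0.006),
    scz_onset = list(mean = 23, sd = 5, min = 12, max = 35),
    covariate_shifts = c(pgs_edu = -0.4, infection = 0.3),
    hospitalization_mean = 0.8)
  low <- class_spec(
    w[5],
    base(F1 = 0.004, F3 = 0.004, F4 = 0.004),
    scz_onset = list(mean = 24, sd = 5, min = 12, max = 35),
    covariate_shifts = numeric(0),
    hospitalization_mean = 0.3)
  list(childhood = childhood, adult = adult, mood = mood,
       substance = substance, low = low)
}

#' Configure the synthetic registry generator
#'
#' The defaults emulate the study conditions of a Danish register birth
#' cohort: births 1981--2002, follow-up to the end of 2016 (so observed
#' sequence lengths vary between about 14 and 36 years), eight comorbidity
#' categories, two age- and sex-matched controls per case, and weak yearly
#' death and emigration hazards matching the handful of such events seen
#' per thousand person-years in register cohorts.
#'
#' @param n_cases number of cases (each case carries an index diagnosis)
#' @param n_controls_per_case matched controls per case (default 2)
#' @param birth_window integer `c(first_year, last_year)` of birth years
#' @param followup_end administrative end of follow-up (`Date`)
#' @param categories diagnosis category labels
#' @param latent_classes list of [class_spec()]; weights must sum to 1
#' @param control_class a [class_spec()] used for controls (its weight is
#'   ignored); defaults to low population hazards (about 0.2%/year per
#'   category)
#' @param death_hazard,emigration_hazard per-year probabilities in `[0, 1]`
#' @param covariates list describing covariates to generate; each element
#'   is `list(type = "continuous", mean=, sd=)` or
#'   `list(type = "binary", prob=)`, named by covariate
#' @param seed integer seed making [simulate_cohort()] reproducible
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_cases = 500,
                       n_controls_per_case = 2,
                       birth_window = c(1981L, 2002L),
                       followup_end = as.Date("2016-12-31"),
                       categories = default_categories(),
                       latent_classes = default_latent_classes(categories),
                       control_class = NULL,
                       death_hazard = 0.001,
                       emigration_hazard = 0.0005,
                       covariates = default_covariates(),
                       seed = 1L) {
  if (death_hazard < 0 || death_hazard > 1 ||
      emigration_hazard < 0 || emigration_hazard > 1)
    stop("death and emigration hazards must be probabilities in [0, 1]")
  if (birth_window[2] < birth_window[1])
    stop("birth window is empty")
  w <- vapply(latent_classes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop("latent class weights must sum to 1 (got ", sum(w), ")")
  if (is.null(names(latent_classes)))
    names(latent_classes) <- paste0("class", seq_along(latent_classes))
  for (cl in latent_classes) {
    if (!identical(sort(names(cl$base_hazard)), sort(categories)))
      stop("class base_hazard names must match the categories")
  }
  if (is.null(control_class)) {
    h <- stats::setNames(rep(0.002, length(categories)), categories)
    control_class <- class_spec(1, h, hospitalization_mean = 0)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls_per_case = as.integer(n_controls_per_case),
                 birth_window = as.integer(birth_window),
                 followup_end = as.Date(followup_end),
                 categories = categories,
                 latent_classes = latent_classes,
                 control_class = control_class,
                 death_hazard = death_hazard,
                 emigration_hazard = emigration_hazard,
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default covariate definitions for the generator
#'
#' Continuous maternal age (years) and a standardized polygenic-score-like
#' covariate, plus a binary hospital-treated-infection indicator. These
#' stand in for the registry and genetic risk factors of a real cohort.
#'
#' @return named list of covariate definitions
#' @export
default_covariates <- function() {
  list(maternal_age = list(type = "continuous", mean = 27, sd = 5),
       pgs_edu = list(type = "continuous", mean = 0, sd = 1),
       infection = list(type = "binary", prob = 0.25))
}

DAYS_PER_YEAR <- 365.25

# yearly probability -> constant hazard rate with the same 1-year survival
rate_from_hazard <- function(h) ifelse(h >= 1, Inf, -log1p(-h))

# first-event ages for all categories of one person: competing exponentials
# with piecewise-constant rates that switch at each realized diagnosis date
simulate_person_events <- function(base_rate, mult, censor_age) {
  C <- length(base_rate)
  diagnosed <- rep(FALSE, C)
  ages <- rep(NA_real_, C)
  t <- 0
  repeat {
    rates <- base_rate
    for (a in which(diagnosed)) rates <- rates * mult[a, ]
    rates[diagnosed] <- 0
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t >= censor_age) break
    j <- sample.int(C, 1L, prob = rates)
    diagnosed[j] <- TRUE
    ages[j] <- t
  }
  ages
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) return((lo + hi) / 2)
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

#' Simulate a registry-like cohort with planted latent structure
#'
#' Draws cases from the configured latent-class mixture and matched
#' controls by duplicating case birth dates and sexes. Comorbidity
#' first-diagnosis events arise from competing exponential clocks whose
#' rates switch at each realized prior diagnosis (so planted pairwise
#' multipliers are hazard ratios), censoring from yearly death/emigration
#' hazards and the administrative end of follow-up. Covariates receive the
#' class-specific shifts; hospitalization outcomes are negative binomial
#' with a class-dependent yearly mean over post-onset follow-up.
#'
#' @param config a [sim_config()]
#' @param seed optional integer overriding `config$seed`
#' @return an object of class `cohort`: a list of data frames
#'   `persons` (`person_id,sex,birth_date,censor_date,censor_reason,
#'   scz_first_date,group`), `events` (`person_id,category,first_date`),
#'   `covariates` (one column per covariate plus the outcome columns
#'   `n_hospitalizations,days_hospitalized`) and `truth`
#'   (`person_id,latent_class`, cases only; simulation truth, not an
#'   observable)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  cats <- config$categories
  C <- length(cats)
  classes <- config$latent_classes
  w <- vapply(classes, `[[`, numeric(1), "weight")
  n_cases <- config$n_cases
  n_ctl <- config$n_cases * config$n_controls_per_case
  n <- n_cases + n_ctl

  # cases first, then their matched controls (same birth date and sex)
  birth_start <- as.Date(paste0(config$birth_window[1], "-01-01"))
  birth_end <- as.Date(paste0(config$birth_window[2], "-12-31"))
  case_birth <- birth_start +
    floor(stats::runif(n_cases) * (as.numeric(birth_end - birth_start) + 1))
  case_sex <- ifelse(stats::runif(n_cases) < 0.56, "M", "F")
  case_class <- if (length(classes) == 1L) rep(1L, n_cases) else
    sample.int(length(classes), n_cases, replace = TRUE, prob = w)

  birth <- c(case_birth, rep(case_birth, config$n_controls_per_case))
  sex <- c(case_sex, rep(case_sex, config$n_controls_per_case))
  group <- rep(c("case", "control"), c(n_cases, n_ctl))
  ids <- sprintf("P%05d", seq_len(n))

  max_follow <- as.numeric(config$followup_end - birth) / DAYS_PER_YEAR
  death_rate <- rate_from_hazard(config$death_hazard)
  emi_rate <- rate_from_hazard(config$emigration_hazard)
  t_death <- if (death_rate > 0) stats::rexp(n, death_rate) else rep(Inf, n)
  t_emi <- if (emi_rate > 0) stats::rexp(n, emi_rate) else rep(Inf, n)
  censor_age <- pmin(t_death, t_emi, max_follow)
  censor_reason <- ifelse(censor_age == max_follow, "end_of_followup",
                          ifelse(t_death <= t_emi, "death", "emigration"))
  censor_date <- birth + round(censor_age * DAYS_PER_YEAR)
  censor_date[censor_reason == "end_of_followup"] <- config$followup_end

  cov_defs <- config$covariates
  cov_names <- names(cov_defs)
  covs <- matrix(NA_real_, n, length(cov_defs),
                 dimnames = list(NULL, cov_names))

  ev_id <- character(0); ev_cat <- character(0); ev_date <- numeric(0)
  scz_date <- rep(as.Date(NA), n)
  n_hosp <- numeric(n); days_hosp <- numeric(n)

  for (i in seq_len(n)) {
    spec <- if (group[i] == "case") classes[[case_class[i]]] else
      config$control_class
    base_rate <- rate_from_hazard(spec$base_hazard[cats])
    ages <- simulate_person_events(base_rate, spec$pair_multipliers[cats, cats,
                                                                    drop = FALSE],
                                   censor_age[i])
    hit <- which(!is.na(ages))
    if (length(hit)) {
      d <- birth[i] + pmin(round(ages[hit] * DAYS_PER_YEAR),
                           as.numeric(censor_date[i] - birth[i]))
      ev_id <- c(ev_id, rep(ids[i], length(hit)))
      ev_cat <- c(ev_cat, cats[hit])
      ev_date <- c(ev_date, as.numeric(d))
    }
    if (group[i] == "case") {
      on <- spec$scz_onset
      onset_age <- rtruncnorm1(on$mean, on$sd,
                               max(min(on$min, censor_age[i] / 2), 0.5),
                               min(on$max, censor_age[i]))
      scz_date[i] <- birth[i] + min(round(onset_age * DAYS_PER_YEAR),
                                    as.numeric(censor_date[i] - birth[i]))
      post_years <- max(censor_age[i] - onset_age, 0)
      mu <- spec$hospitalization_mean * post_years
      n_hosp[i] <- if (mu > 0)
        stats::rnbinom(1, size = 1.2, mu = mu) else 0
      days_hosp[i] <- if (n_hosp[i] > 0)
        sum(1 + stats::rpois(n_hosp[i], 13)) else 0
    }
    for (k in seq_along(cov_defs)) {
      def <- cov_defs[[k]]
      shift <- spec$covariate_shifts[cov_names[k]]
      shift <- if (is.na(shift)) 0 else shift
      covs[i, k] <- if (def$type == "continuous")
        stats::rnorm(1, def$mean + shift, def$sd)
      else
        as.numeric(stats::runif(1) < stats::plogis(stats::qlogis(def$prob) + shift))
    }
  }

  persons <- data.frame(person_id = ids, sex = sex,
                        birth_date = birth, censor_date = censor_date,
                        censor_reason = censor_reason,
                        scz_first_date = scz_date,
                        group = group, stringsAsFactors = FALSE)
  events <- data.frame(person_id = ev_id, category = ev_cat,
                       first_date = as.Date(ev_date, origin = "1970-01-01"),
                       stringsAsFactors = FALSE)
  events <- events[order(events$person_id, events$first_date, events$category), ,
                   drop = FALSE]
  rownames(events) <- NULL
  covariates <- data.frame(person_id = ids, covs,
                           n_hospitalizations = n_hosp,
                           days_hospitalized = days_hosp,
                           stringsAsFactors = FALSE)
  truth <- data.frame(person_id = ids[group == "case"],
                      latent_class = names(classes)[case_class],
                      stringsAsFactors = FALSE)
  structure(list(persons = persons, events = events,
                 covariates = covariates, truth = truth,
                 categories = cats),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic registry cohort:", nrow(x$persons), "persons (",
      sum(x$persons$group == "case"), "cases ),",
      nrow(x$events), "first-diagnosis events\n")
  invisible(x)
}
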