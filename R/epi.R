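#' Cumulative incidence of a diagnosis category under right censoring
#'
#' One-minus-Kaplan-Meier on the age scale; persons are censored at the
#' earliest of death, emigration or administrative end of follow-up.
#' Optionally decomposes the estimate at `at_age` into the parts
#' attributable to events before vs after the index (schizophrenia)
#' diagnosis, by apportioning the overall estimate by the observed
#' fraction of first events that preceded the index date.
#'
#' @param cohort a `cohort` object
#' @param category diagnosis category label
#' @param at_age age (years) at which to evaluate the estimate
#' @param group persons to include (`"case"`, `"control"`, `"all"`)
#' @param split_by_index if `TRUE`, also report the before/after-index
#'   decomposition (cases only make sense here)
#' @param conf_level confidence level (default 0.95)
#' @return list with `estimate`, `ci_low`, `ci_high`, `n`, `n_events`,
#'   and when `split_by_index` also `before_fraction`, `before`, `after`
#' @export
cumulative_incidence <- function(cohort, category, at_age,
                                 group = "case", split_by_index = FALSE,
                                 conf_level = 0.95) {
  p <- cohort$persons
  if (group != "all") p <- p[p$group == group, , drop = FALSE]
  if (nrow(p) == 0L) stop("no persons in group '", group, "'")
  e <- cohort$events[cohort$events$category == category, ]
  ev_date <- e$first_date[match(p$person_id, e$person_id)]
  censor_age <- as.numeric(p$censor_date - p$birth_date) / DAYS_PER_YEAR
  ev_age <- as.numeric(ev_date - p$birth_date) / DAYS_PER_YEAR
  status <- as.integer(!is.na(ev_age))
  time <- ifelse(status == 1L, ev_age, censor_age)
  if (max(time) < at_age)
    stop("no person remains under observation at age ", at_age)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1,
                           conf.int = conf_level)
  s <- summary(fit, times = at_age)
  out <- list(estimate = 1 - s$surv,
              ci_low = 1 - s$upper, ci_high = 1 - s$lower,
              n = nrow(p), n_events = sum(status))
  if (split_by_index) {
    idx_age <- as.numeric(p$scz_first_date - p$birth_date) / DAYS_PER_YEAR
    hit <- status == 1L & time <= at_age
    n_hit <- sum(hit)
    before_frac <- if (n_hit == 0) NA_real_ else
      sum(hit & !is.na(idx_age) & ev_age <= idx_age) / n_hit
    out$before_fraction <- before_frac
    out$before <- out$estimate * before_frac
    out$after <- out$estimate * (1 - before_frac)
  }
  out
}

#' Relative risk from a 2x2 table with a log-method confidence interval
#'
#' `rr = (a/n1) / (b/n2)` with the interval
#' `exp(log rr +/- z * sqrt(1/a - 1/n1 + 1/b - 1/n2))`.
#'
#' @param a events among exposed (cases); `n1` exposed total
#' @param b events among unexposed (controls); `n2` unexposed total
#' @param n1,n2 group sizes
#' @param alpha two-sided significance level (default 0.05)
#' @return list with `rr`, `ci_low`, `ci_high`, `alpha`
#' @examples
#' relative_risk(370, 5432, 120, 10864)  # rr 6.2, CI 5.0-7.6
#' @export
relative_risk <- function(a, n1, b, n2, alpha = 0.05) {
  stopifnot(a == round(a), b == round(b), n1 == round(n1), n2 == round(n2))
  if (a < 0 || b < 0 || a > n1 || b > n2)
    stop("need 0 <= a <= n1 and 0 <= b <= n2")
  if (a == 0 || b == 0)
    stop("zero event cell: the log-method interval is undefined; ",
         "consider a continuity correction")
  rr <- (a / n1) / (b / n2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  z <- stats::qnorm(1 - alpha / 2)
  list(rr = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
       alpha = alpha)
}

#' Bonferroni multiple-testing threshold
#'
#' @param alpha family-wise level
#' @param m number of tests
#' @return `alpha / m`, carrying a `"display"` attribute rounded to two
#'   significant digits for reporting (e.g. 0.05/56 displays as 0.00089)
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  thr <- alpha / m
  attr(thr, "display") <- signif(thr, 2)
  thr
}

# counting-process episode split for one person and one ordered pair:
# follow-up to the first B event (or censoring), cut at the first A date
episode_split_pair <- function(t_event, status, t_exposure) {
  if (is.na(t_exposure) || t_exposure >= t_event) {
    data.frame(tstart = 0, tstop = t_event, status = status, prior = 0L)
  } else if (t_exposure <= 0) {
    # exposed from the start of follow-up: no unexposed episode to split
    data.frame(tstart = 0, tstop = t_event, status = status, prior = 1L)
  } else {
    data.frame(tstart = c(0, t_exposure), tstop = c(t_exposure, t_event),
               status = c(0L, status), prior = c(0L, 1L))
  }
}

#' Time-dependent Cox hazards for all ordered diagnosis pairs
#'
#' For every ordered pair (A, B) of categories, fits a Cox proportional
#' hazards model on the age scale for the first B diagnosis, with a
#' time-varying indicator of a prior A diagnosis (episode-splitting each
#' person's follow-up at their first A date) and sex as a fixed
#' covariate. Age adjustment is absorbed into the baseline hazard by
#' using age as the time scale. Significance is judged against a
#' Bonferroni threshold for the `C * (C - 1)` pairs tested.
#'
#' @param cohort a `cohort` object
#' @param categories categories to cross (default: the cohort's)
#' @param alpha family-wise level (default 0.05)
#' @param group persons to include (default cases, mirroring a
#'   within-patient comorbidity analysis)
#' @return data frame with one row per ordered pair: `first`, `second`,
#'   `hr`, `se_loghr`, `ci_low`, `ci_high`, `wald_p`,
#'   `significant_after_bonferroni`, `flagged` (inestimable or
#'   non-converged pairs)
#' @export
pairwise_hazards <- function(cohort, categories = NULL, alpha = 0.05,
                             group = "case") {
  p <- cohort$persons
  if (group != "all") p <- p[p$group == group, , drop = FALSE]
  if (is.null(categories)) categories <- cohort$categories
  C <- length(categories)
  if (C < 2L) stop("need at least two categories")
  m <- C * (C - 1L)
  thr <- bonferroni(alpha, m)
  censor_age <- as.numeric(p$censor_date - p$birth_date) / DAYS_PER_YEAR
  ev <- cohort$events
  age_of <- function(cat) {
    e <- ev[ev$category == cat, ]
    d <- e$first_date[match(p$person_id, e$person_id)]
    as.numeric(d - p$birth_date) / DAYS_PER_YEAR
  }
  ages <- lapply(stats::setNames(categories, categories), age_of)
  sex_num <- as.integer(p$sex == "M")
  out <- list()
  for (A in categories) for (B in categories) {
    if (A == B) next
    tA <- ages[[A]]; tB <- ages[[B]]
    status <- as.integer(!is.na(tB))
    t_event <- ifelse(status == 1L, tB, censor_age)
    rows <- lapply(seq_len(nrow(p)), function(i) {
      if (t_event[i] <= 0) return(NULL)
      d <- episode_split_pair(t_event[i], status[i], tA[i])
      d$sex <- sex_num[i]
      d
    })
    dat <- do.call(rbind, rows)
    res <- data.frame(first = A, second = B, hr = NA_real_,
                      se_loghr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, wald_p = NA_real_,
                      significant_after_bonferroni = FALSE, flagged = TRUE)
    n_exposed_events <- sum(dat$status == 1L & dat$prior == 1L)
    n_unexposed_events <- sum(dat$status == 1L & dat$prior == 0L)
    if (sum(dat$prior) > 0 && n_exposed_events + n_unexposed_events > 0) {
      fit <- tryCatch(
        survival::coxph(survival::Surv(tstart, tstop, status) ~ prior + sex,
                        data = dat),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && is.finite(stats::coef(fit)["prior"])) {
        co <- summary(fit)$coefficients
        beta <- co["prior", "coef"]; se <- co["prior", "se(coef)"]
        if (is.finite(se) && se < 50) {
          res$hr <- exp(beta); res$se_loghr <- se
          res$ci_low <- exp(beta - stats::qnorm(1 - alpha / 2) * se)
          res$ci_high <- exp(beta + stats::qnorm(1 - alpha / 2) * se)
          res$wald_p <- co["prior", "Pr(>|z|)"]
          res$significant_after_bonferroni <- res$wald_p < thr
          res$flagged <- FALSE
        }
      }
    }
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  attr(res, "bonferroni_threshold") <- as.numeric(thr)
  attr(res, "n_tests") <- m
  res
}
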