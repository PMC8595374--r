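#' Write a cohort to a directory of CSV files
#'
#' Writes `persons.csv`, `events.csv`, `covariates.csv` and (when the
#' cohort carries simulation truth) `truth.csv`. Dates are ISO-8601;
#' absent values (e.g. `scz_first_date` for controls) are empty fields.
#'
#' @param cohort a `cohort` object (see [simulate_cohort()])
#' @param path directory to write into (created if missing)
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$persons
  p$birth_date <- format(p$birth_date)
  p$censor_date <- format(p$censor_date)
  p$scz_first_date <- ifelse(is.na(p$scz_first_date), "",
                             format(p$scz_first_date))
  utils::write.csv(p, file.path(path, "persons.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  e <- cohort$events
  e$first_date <- format(e$first_date)
  utils::write.csv(e, file.path(path, "events.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(cohort$covariates, file.path(path, "covariates.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(cohort$truth) && nrow(cohort$truth) > 0)
    utils::write.csv(cohort$truth, file.path(path, "truth.csv"),
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

parse_date_col <- function(x, file, what) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonempty <- !is.na(x) & x != ""
  parsed <- as.Date(x[nonempty], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonempty)[which(is.na(parsed))[1]]
    stop("malformed ", what, " in ", file, " at data line ", bad,
         ": '", x[bad], "' is not an ISO-8601 date")
  }
  out[nonempty] <- parsed
  out
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of [write_cohort()]. All dates are validated and every event is
#' checked to lie inside its person's `[birth_date, censor_date]` window;
#' violations are reported with the offending file and line.
#'
#' @param path directory containing `persons.csv`, `events.csv` and
#'   optionally `covariates.csv` / `truth.csv`
#' @return a `cohort` object
#' @export
read_cohort <- function(path) {
  pf <- file.path(path, "persons.csv")
  ef <- file.path(path, "events.csv")
  if (!file.exists(pf)) stop("missing persons file: ", pf)
  if (!file.exists(ef)) stop("missing events file: ", ef)
  p <- utils::read.csv(pf, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("person_id", "sex", "birth_date", "censor_date", "censor_reason")
  if (!all(need %in% names(p)))
    stop("persons.csv must have columns ", paste(need, collapse = ", "))
  p$birth_date <- parse_date_col(p$birth_date, "persons.csv", "birth_date")
  p$censor_date <- parse_date_col(p$censor_date, "persons.csv", "censor_date")
  if (!"scz_first_date" %in% names(p)) p$scz_first_date <- ""
  p$scz_first_date <- parse_date_col(p$scz_first_date, "persons.csv",
                                     "scz_first_date")
  if (!"group" %in% names(p))
    p$group <- ifelse(is.na(p$scz_first_date), "control", "case")
  bad <- which(p$censor_date < p$birth_date)
  if (length(bad))
    stop("persons.csv data line ", bad[1], ": censor_date before birth_date")
  ok_reason <- p$censor_reason %in% c("death", "emigration", "end_of_followup")
  if (!all(ok_reason))
    stop("persons.csv data line ", which(!ok_reason)[1],
         ": unknown censor_reason '", p$censor_reason[!ok_reason][1], "'")

  e <- utils::read.csv(ef, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (nrow(e) == 0)
    e <- data.frame(person_id = character(0), category = character(0),
                    first_date = as.Date(character(0)),
                    stringsAsFactors = FALSE)
  else {
    if (!all(c("person_id", "category", "first_date") %in% names(e)))
      stop("events.csv must have columns person_id, category, first_date")
    e$first_date <- parse_date_col(e$first_date, "events.csv", "first_date")
    idx <- match(e$person_id, p$person_id)
    if (anyNA(idx))
      stop("events.csv data line ", which(is.na(idx))[1],
           ": unknown person_id '", e$person_id[is.na(idx)][1], "'")
    bad <- which(e$first_date < p$birth_date[idx] |
                   e$first_date > p$censor_date[idx])
    if (length(bad))
      stop("events.csv data line ", bad[1],
           ": event date outside [birth_date, censor_date] for person ",
           e$person_id[bad[1]])
    dup <- duplicated(e[, c("person_id", "category")])
    if (any(dup))
      stop("events.csv data line ", which(dup)[1],
           ": duplicate first diagnosis for person ", e$person_id[dup][1])
  }

  cf <- file.path(path, "covariates.csv")
  covariates <- if (file.exists(cf))
    utils::read.csv(cf, stringsAsFactors = FALSE) else NULL
  if (!is.null(covariates)) {
    num <- vapply(covariates, is.numeric, logical(1))
    covariates[num] <- lapply(covariates[num], as.numeric)
  }
  tf <- file.path(path, "truth.csv")
  truth <- if (file.exists(tf))
    utils::read.csv(tf, stringsAsFactors = FALSE) else NULL

  structure(list(persons = p, events = e, covariates = covariates,
                 truth = truth, categories = sort(unique(e$category))),
            class = "cohort")
}
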