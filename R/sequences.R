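#' Build one person's cumulative-diagnosis state sequence
#'
#' Time is discretized into fixed increments on an age grid anchored at
#' birth. The state of interval `t` (t = 0, 1, ...) is the cumulative set
#' of diagnosis categories whose first-diagnosis date strictly precedes
#' the start of that interval, so a diagnosis made during interval `t`
#' first appears in the state of interval `t + 1`. The observed length is
#' the number of whole increments between birth and censoring, capped at
#' `target_length`.
#'
#' @param birth_date,censor_date the person's observation window (`Date`)
#' @param event_categories,event_dates first-diagnosis events (parallel
#'   vectors; may be empty)
#' @param alphabet a [build_alphabet()] object
#' @param increment interval length in years (1 = yearly; 0.5 and 1/3
#'   give 6- and 4-month grids)
#' @param target_length number of intervals sequences are extended to by
#'   tail imputation downstream (default 36 yearly intervals)
#' @param person_id identifier carried through to outputs
#' @return an object of class `state_sequence`: list with `person_id`,
#'   `observed` (integer bitmask per observed interval), `l_obs`,
#'   `increment`, `target_length` and `birth_year`
#' @export
build_sequence <- function(birth_date, censor_date,
                           event_categories = character(0),
                           event_dates = as.Date(character(0)),
                           alphabet,
                           increment = 1,
                           target_length = 36L,
                           person_id = NA_character_) {
  stopifnot(inherits(alphabet, "state_alphabet"))
  birth_date <- as.Date(birth_date); censor_date <- as.Date(censor_date)
  if (is.na(birth_date) || is.na(censor_date) || censor_date < birth_date)
    stop("invalid observation window for person ", person_id)
  event_dates <- as.Date(event_dates)
  if (length(event_dates) != length(event_categories))
    stop("event categories and dates must be parallel vectors")
  if (length(event_dates) &&
      (any(event_dates < birth_date) || any(event_dates > censor_date)))
    stop("event outside [birth_date, censor_date] for person ", person_id)

  step_days <- increment * DAYS_PER_YEAR
  # interval 0 is always fully determined (no diagnosis can strictly
  # precede birth), so even persons censored within the first increment
  # contribute one observed interval
  l_obs <- min(floor(as.numeric(censor_date - birth_date) / step_days),
               target_length)
  l_obs <- max(as.integer(l_obs), 1L)
  states <- integer(max(l_obs, 0L))
  if (l_obs > 0L) {
    # age (in increments) at which each event starts counting: strictly
    # before the interval start, so an event exactly on a boundary counts
    # from the next interval
    mask <- 0L
    if (length(event_dates)) {
      ev_step <- as.numeric(event_dates - birth_date) / step_days
      bits <- bitwShiftL(1L, match(event_categories, alphabet$categories) - 1L)
      if (anyNA(bits))
        stop("event category outside the alphabet for person ", person_id)
      ord <- order(ev_step)
      ev_step <- ev_step[ord]; bits <- bits[ord]
      k <- 1L
      for (t in seq_len(l_obs)) {
        start <- t - 1
        while (k <= length(ev_step) && ev_step[k] < start) {
          mask <- bitwOr(mask, bits[k]); k <- k + 1L
        }
        states[t] <- mask
      }
    }
  }
  structure(list(person_id = person_id,
                 observed = states,
                 l_obs = l_obs,
                 increment = increment,
                 target_length = as.integer(target_length),
                 birth_year = as.integer(format(birth_date, "%Y"))),
            class = "state_sequence")
}

#' Build state sequences for every person in a cohort
#'
#' Cases only by default: the trajectory analysis describes the comorbidity
#' course of the index cohort, while controls enter only the
#' epidemiological contrasts.
#'
#' @param cohort a `cohort` object
#' @param alphabet a [build_alphabet()]; defaults to an alphabet over the
#'   cohort's categories
#' @param increment interval length in years
#' @param target_length grid length sequences are later extended to
#' @param group which persons to include (`"case"`, `"control"` or
#'   `"all"`)
#' @return an object of class `sequence_set`: list of `state_sequence`
#'   objects plus the shared `alphabet`, `increment` and `target_length`
#' @export
build_sequences <- function(cohort,
                            alphabet = build_alphabet(cohort$categories),
                            increment = 1,
                            target_length = 36L,
                            group = "case") {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$persons
  if (group != "all") p <- p[p$group == group, , drop = FALSE]
  ev_split <- split(cohort$events[, c("category", "first_date")],
                    cohort$events$person_id)
  seqs <- lapply(seq_len(nrow(p)), function(i) {
    ev <- ev_split[[p$person_id[i]]]
    build_sequence(p$birth_date[i], p$censor_date[i],
                   if (is.null(ev)) character(0) else ev$category,
                   if (is.null(ev)) as.Date(character(0)) else ev$first_date,
                   alphabet, increment, target_length,
                   person_id = p$person_id[i])
  })
  structure(list(sequences = seqs, alphabet = alphabet,
                 increment = increment,
                 target_length = as.integer(target_length)),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  l <- vapply(x$sequences, `[[`, integer(1), "l_obs")
  cat("Sequence set:", length(x$sequences), "sequences,",
      "increment", x$increment, "y, observed lengths",
      min(l), "-", max(l), "of", x$target_length, "\n")
  invisible(x)
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("State sequence", x$person_id, "(", x$l_obs, "observed of",
      x$target_length, "intervals )\n")
  invisible(x)
}

#' Export a sequence set as CSV
#'
#' One row per person: `person_id,L_obs,s_0,s_1,...` with states written
#' as sorted `"+"`-joined category labels and the empty set as `NONE`.
#' Only observed positions are written; trailing cells are empty.
#'
#' @param seqset a [build_sequences()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sequences <- function(seqset, path) {
  stopifnot(inherits(seqset, "sequence_set"))
  tl <- seqset$target_length
  cats <- seqset$alphabet$categories
  rows <- vapply(seqset$sequences, function(s) {
    lab <- c(state_label(s$observed, cats), rep("", tl - s$l_obs))
    paste(c(s$person_id, s$l_obs, lab), collapse = ",")
  }, character(1))
  header <- paste(c("person_id", "L_obs",
                    paste0("s_", seq_len(tl) - 1L)), collapse = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}
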