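#' Estimate a first-order Markov transition model from observed sequences
#'
#' Maximum-likelihood, time-homogeneous estimate pooled over all persons
#' and all observed interval pairs: `P(s -> t)` is the number of observed
#' `(s at i, t at i+1)` transitions divided by the number of observed
#' intervals in state `s` that have an observed successor. Because the
#' sequences are cumulative, the support of each row is restricted to
#' supersets of the origin state. States that occur in the data but never
#' as a transition origin receive a self-loop row.
#'
#' @param seqset a [build_sequences()] result (or a plain list of
#'   `state_sequence` objects)
#' @return an object of class `transition_model`: list with `P` (dense
#'   row-stochastic matrix over the states seen in the data, dimnames =
#'   bitmask keys), `states` (integer masks) and `estimated_from`
#'   (number of observed transitions)
#' @export
estimate_transitions <- function(seqset) {
  seqs <- if (inherits(seqset, "sequence_set")) seqset$sequences else seqset
  from <- integer(0); to <- integer(0)
  for (s in seqs) {
    if (s$l_obs >= 2L) {
      from <- c(from, s$observed[-s$l_obs])
      to <- c(to, s$observed[-1L])
    }
  }
  if (length(from) == 0L)
    stop("no observed transitions: need at least one sequence of length >= 2")
  states <- sort(unique(c(from, to,
                          unlist(lapply(seqs, `[[`, "observed")))))
  key <- as.character(states)
  P <- matrix(0, length(states), length(states), dimnames = list(key, key))
  tab <- table(factor(as.character(from), levels = key),
               factor(as.character(to), levels = key))
  P[] <- as.numeric(tab)
  rs <- rowSums(P)
  for (i in seq_along(states)) {
    if (rs[i] > 0) P[i, ] <- P[i, ] / rs[i] else P[i, i] <- 1
  }
  structure(list(P = P, states = states,
                 estimated_from = length(from)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("First-order Markov transition model:", length(x$states),
      "states, estimated from", x$estimated_from, "transitions\n")
  invisible(x)
}

# extend a transition model with self-loop rows for additional states
# (the same convention used for states never observed as origins), so
# sequences from outside the estimation cohort can be imputed
augment_transitions <- function(model, states) {
  extra <- setdiff(as.integer(states), model$states)
  if (length(extra) == 0L) return(model)
  all_states <- sort(c(model$states, extra))
  key <- as.character(all_states)
  P <- matrix(0, length(key), length(key), dimnames = list(key, key))
  P[rownames(model$P), colnames(model$P)] <- model$P
  for (s in as.character(extra)) P[s, s] <- 1
  model$P <- P
  model$states <- all_states
  model
}

#' Impute the censored tail of a sequence as state distributions
#'
#' For intervals beyond the observed length, the probability of each state
#' is propagated by the first-order chain: the first imputed interval is
#' the one-step transition row of the last observed state, and each later
#' interval multiplies by the transition matrix again, out to
#' `target_length`.
#'
#' @param seq a `state_sequence` with `l_obs >= 1`
#' @param model a [estimate_transitions()] result
#' @return a numeric matrix with `target_length - l_obs` rows (possibly
#'   zero), one distribution per imputed interval; columns named by state
#'   bitmask keys
#' @export
impute_tail <- function(seq, model) {
  stopifnot(inherits(seq, "state_sequence"),
            inherits(model, "transition_model"))
  if (seq$l_obs < 1L) stop("cannot impute a tail from an empty sequence")
  n_tail <- seq$target_length - seq$l_obs
  key <- colnames(model$P)
  tail <- matrix(0, max(n_tail, 0L), length(key),
                 dimnames = list(NULL, key))
  if (n_tail <= 0L) return(tail)
  last <- as.character(seq$observed[seq$l_obs])
  if (!last %in% key)
    stop("last observed state ", last, " is not in the transition model")
  p <- model$P[last, ]
  for (i in seq_len(n_tail)) {
    tail[i, ] <- p
    if (i < n_tail) p <- as.numeric(p %*% model$P)
  }
  tail
}
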