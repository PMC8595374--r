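#' Expected substitution cost between observed states or state distributions
#'
#' Alignment positions may be observed states (integer bitmask) or, past a
#' person's censoring date, probability distributions over states (named
#' numeric vector, names = bitmask keys). The cost of aligning two
#' positions is the expectation of the substitution cost under the
#' distribution(s): observed/observed reduces to [substitution_cost()],
#' observed/imputed is the probability-weighted mean cost, and
#' imputed/imputed takes the double expectation assuming the two chains
#' are independent.
#'
#' @param x,y an integer state bitmask (length 1) or a named numeric
#'   probability vector over bitmask keys
#' @param model a [cost_model()]
#' @return a single expected cost
#' @export
position_cost <- function(x, y, model = cost_model()) {
  px <- as_state_distribution(x)
  py <- as_state_distribution(y)
  sx <- as.integer(names(px)); sy <- as.integer(names(py))
  cm <- outer(sx, sy, function(a, b) substitution_cost(a, b, model))
  as.numeric(px %*% cm %*% py)
}

# normalize the two accepted position encodings to a probability vector
as_state_distribution <- function(x) {
  if (is.null(names(x))) {
    if (length(x) != 1L)
      stop("an observed position must be a single state bitmask")
    return(stats::setNames(1, as.character(as.integer(x))))
  }
  if (abs(sum(x) - 1) > 1e-9)
    stop("state distribution is not normalized (sums to ", sum(x), ")")
  if (any(x < 0)) stop("state distribution has negative mass")
  x
}

# target_length x n_states probability matrix for one extended sequence:
# point masses on observed intervals, imputed distributions on the tail
extended_prob_matrix <- function(seq, tail, state_key) {
  TL <- seq$l_obs + nrow(tail)
  E <- matrix(0, TL, length(state_key), dimnames = list(NULL, state_key))
  obs_key <- as.character(seq$observed)
  if (!all(obs_key %in% state_key))
    stop("observed state outside the working state set")
  E[cbind(seq_len(seq$l_obs), match(obs_key, state_key))] <- 1
  if (nrow(tail) > 0) {
    if (!all(colnames(tail) %in% state_key))
      stop("imputed tail states outside the working state set")
    E[seq$l_obs + seq_len(nrow(tail)), match(colnames(tail), state_key)] <- tail
  }
  E
}

#' Optimal-matching distance between two (extended) sequences
#'
#' Runs the global-alignment dynamic program over the two position
#' vectors, each position priced by [position_cost()] and indels by the
#' model's indel cost. When imputed tails are supplied each sequence must
#' extend exactly to its `target_length`.
#'
#' @param seq_a,seq_b `state_sequence` objects
#' @param tails_a,tails_b imputed-tail matrices from [impute_tail()]
#'   (`NULL` = no imputation; the observed positions alone are aligned)
#' @param model a [cost_model()]
#' @return the minimal total edit cost (symmetric in its arguments)
#' @export
om_distance <- function(seq_a, seq_b, tails_a = NULL, tails_b = NULL,
                        model = cost_model()) {
  empty_tail <- function(s) matrix(0, 0, 0)
  ta <- if (is.null(tails_a)) empty_tail(seq_a) else tails_a
  tb <- if (is.null(tails_b)) empty_tail(seq_b) else tails_b
  if (!is.null(tails_a) && seq_a$l_obs + nrow(ta) != seq_a$target_length)
    stop("sequence a is not extended to its target length after imputation")
  if (!is.null(tails_b) && seq_b$l_obs + nrow(tb) != seq_b$target_length)
    stop("sequence b is not extended to its target length after imputation")
  if (!is.null(tails_a) && !is.null(tails_b) &&
      seq_a$target_length != seq_b$target_length)
    stop("length mismatch after imputation: ", seq_a$target_length,
         " vs ", seq_b$target_length)
  states <- sort(unique(c(seq_a$observed, seq_b$observed,
                          as.integer(colnames(ta)), as.integer(colnames(tb)))))
  key <- as.character(states)
  Cmat <- cost_matrix(states, model)
  Ea <- extended_prob_matrix(seq_a, ta, key)
  Eb <- extended_prob_matrix(seq_b, tb, key)
  pc <- (Ea %*% Cmat) %*% t(Eb)
  .om_dp(pc, model$indel_cost)
}

#' Censoring-aware pairwise optimal-matching dissimilarity matrix
#'
#' Imputes every censored tail once from the (population-wide) transition
#' model, then aligns every pair of extended sequences. Because every
#' sequence is extended to the same target length, the resulting
#' dissimilarity does not depend on the observed sequence lengths.
#'
#' @param seqset a [build_sequences()] result
#' @param model a [cost_model()]
#' @param transition_model a [estimate_transitions()] result; by default
#'   estimated from `seqset` itself (only needed when some sequence is
#'   censored before `target_length`)
#' @return symmetric numeric matrix with zero diagonal, person ids as
#'   dimnames
#' @export
pairwise_matrix <- function(seqset, model = cost_model(),
                            transition_model = NULL) {
  stopifnot(inherits(seqset, "sequence_set"))
  seqs <- seqset$sequences
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  prep <- prepare_extended(seqs, model, transition_model)
  D <- matrix(0, n, n,
              dimnames = list(vapply(seqs, `[[`, character(1), "person_id"),
                              vapply(seqs, `[[`, character(1), "person_id")))
  indel <- model$indel_cost
  for (i in seq_len(n - 1L)) {
    Ai <- prep$A[[i]]
    for (j in (i + 1L):n) {
      d <- .om_dp(Ai %*% prep$tE[[j]], indel)
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

# shared precomputation: per-sequence extended probability matrices E,
# their cost-weighted versions A = E %*% C, and transposes of E
prepare_extended <- function(seqs, model, transition_model,
                             extra_states = integer(0)) {
  needs_imp <- any(vapply(seqs, function(s) s$l_obs < s$target_length,
                          logical(1)))
  if (needs_imp && is.null(transition_model))
    transition_model <- estimate_transitions(seqs)
  if (needs_imp)
    transition_model <- augment_transitions(
      transition_model, unique(unlist(lapply(seqs, `[[`, "observed"))))
  model_states <- if (needs_imp) transition_model$states else integer(0)
  states <- sort(unique(c(unlist(lapply(seqs, `[[`, "observed")),
                          model_states, extra_states)))
  key <- as.character(states)
  Cmat <- cost_matrix(states, model)
  E <- lapply(seqs, function(s) {
    tail <- if (s$l_obs < s$target_length)
      impute_tail(s, transition_model) else matrix(0, 0, 0)
    extended_prob_matrix(s, tail, key)
  })
  list(E = E, tE = lapply(E, t), A = lapply(E, function(e) e %*% Cmat),
       states = states, Cmat = Cmat, transition_model = transition_model)
}

#' Distances from new sequences to a reference sequence set
#'
#' Used for replication cohorts: each new sequence is imputed with the
#' *reference* cohort's transition model and aligned against every
#' reference sequence, yielding the distance vectors that
#' [project_new()] maps onto the reference MDS dimensions.
#'
#' @param new_seqset,ref_seqset [build_sequences()] results sharing the
#'   same alphabet and target length
#' @param model a [cost_model()]
#' @param transition_model transition model of the reference cohort; by
#'   default estimated from `ref_seqset`
#' @return matrix with one row per new sequence, one column per reference
#'   sequence
#' @export
cross_distances <- function(new_seqset, ref_seqset, model = cost_model(),
                            transition_model = NULL) {
  if (!identical(new_seqset$alphabet$categories,
                 ref_seqset$alphabet$categories))
    stop("alphabet mismatch between replication and reference cohorts")
  if (length(new_seqset$sequences) == 0L)
    stop("empty replication sequence set")
  if (is.null(transition_model) &&
      any(vapply(c(ref_seqset$sequences, new_seqset$sequences),
                 function(s) s$l_obs < s$target_length, logical(1))))
    transition_model <- estimate_transitions(ref_seqset)
  all_seqs <- c(ref_seqset$sequences, new_seqset$sequences)
  prep <- prepare_extended(all_seqs, model, transition_model)
  n_ref <- length(ref_seqset$sequences)
  n_new <- length(new_seqset$sequences)
  D <- matrix(0, n_new, n_ref,
              dimnames = list(
                vapply(new_seqset$sequences, `[[`, character(1), "person_id"),
                vapply(ref_seqset$sequences, `[[`, character(1), "person_id")))
  for (i in seq_len(n_new)) {
    Ai <- prep$A[[n_ref + i]]
    for (j in seq_len(n_ref))
      D[i, j] <- .om_dp(Ai %*% prep$tE[[j]], model$indel_cost)
  }
  D
}

#' Sensitivity of the dissimilarity matrix to the time-increment size
#'
#' Recomputes the full pairwise matrix on finer grids (keeping the total
#' covered age span fixed) and correlates the lower-triangular entries
#' with the reference increment's matrix.
#'
#' @param cohort a `cohort` object
#' @param increments interval lengths in years; the first is the
#'   reference (default yearly vs 6-month vs 4-month)
#' @param model a [cost_model()]
#' @param target_years age span of the grid (default 36 years)
#' @param group persons to include (default cases)
#' @return named numeric vector of Pearson correlations, one per
#'   non-reference increment
#' @export
increment_sensitivity <- function(cohort, increments = c(1, 0.5, 1 / 3),
                                  model = cost_model(), target_years = 36,
                                  group = "case") {
  if (length(increments) < 2L)
    stop("need the reference increment plus at least one alternative")
  mats <- lapply(increments, function(inc) {
    ss <- build_sequences(cohort, increment = inc,
                          target_length = as.integer(round(target_years / inc)),
                          group = group)
    pairwise_matrix(ss, model)
  })
  ref <- mats[[1]][lower.tri(mats[[1]])]
  if (stats::sd(ref) == 0)
    stop("reference dissimilarity matrix is constant; correlation undefined")
  r <- vapply(mats[-1], function(m) {
    v <- m[lower.tri(m)]
    if (stats::sd(v) == 0)
      stop("degenerate (constant) dissimilarity matrix; correlation undefined")
    stats::cor(ref, v)
  }, numeric(1))
  names(r) <- paste0(signif(increments[-1] * 12, 3), "m")
  r
}

#' Write / read a dissimilarity matrix as delimited text
#'
#' Square tab-separated file with person ids as both header row and first
#' column.
#'
#' @param D symmetric matrix with person-id dimnames
#' @param path file path
#' @return `path` (write) or the matrix (read)
#' @export
write_dissimilarity <- function(D, path) {
  utils::write.table(data.frame(person_id = rownames(D), D,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$person_id
  storage.mode(m) <- "double"
  m
}
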