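# Small in-code fixtures shared across test files.

# construct a state_sequence directly from a vector of bitmask states
make_seq <- function(states, target_length = length(states),
                     id = "S1", increment = 1) {
  structure(list(person_id = id,
                 observed = as.integer(states),
                 l_obs = length(states),
                 increment = increment,
                 target_length = as.integer(target_length),
                 birth_year = 1990L),
            class = "state_sequence")
}

make_seqset <- function(seq_list, categories = c("A", "B"),
                        target_length = NULL) {
  tl <- if (!is.null(target_length)) target_length
  else if (length(seq_list) == 0L) 36L
  else max(vapply(seq_list, `[[`, integer(1), "target_length"))
  structure(list(sequences = seq_list,
                 alphabet = build_alphabet(categories),
                 increment = 1, target_length = as.integer(tl)),
            class = "sequence_set")
}

# independent optimal-matching oracle: minimum cost over all monotone
# matchings between positions of a and b (every edit script corresponds
# to such a matching: matched pairs are substituted, the rest indel'd)
om_oracle <- function(a, b, model = cost_model()) {
  la <- length(a); lb <- length(b)
  best <- (la + lb) * model$indel_cost  # empty matching
  for (k in seq_len(min(la, lb))) {
    ia <- utils::combn(la, k, simplify = FALSE)
    ib <- utils::combn(lb, k, simplify = FALSE)
    for (sa in ia) for (sb in ib) {
      cost <- sum(substitution_cost(a[sa], b[sb], model)) +
        (la - k + lb - k) * model$indel_cost
      if (cost < best) best <- cost
    }
  }
  best
}

# all monotone (cumulative) state sequences of a given length over a
# subset lattice with n_cat categories
monotone_sequences <- function(len, n_cat = 2) {
  states <- 0:(2^n_cat - 1)
  grow <- function(prefix) {
    if (length(prefix) == len) return(list(prefix))
    last <- prefix[length(prefix)]
    nxt <- states[bitwAnd(states, last) == last]  # supersets
    unlist(lapply(nxt, function(s) grow(c(prefix, s))), recursive = FALSE)
  }
  unlist(lapply(states, function(s) grow(s)), recursive = FALSE)
}

# a two-class cohort with disjoint dominant categories, for recovery tests
separable_sim_config <- function(n_cases = 100, seed = 1,
                                 n_classes = 3, ...) {
  cats <- default_categories()
  base <- function(...) {
    h <- stats::setNames(rep(0.001, length(cats)), cats)
    sh <- c(...)
    h[names(sh)] <- sh
    h
  }
  specs <- list(
    class_spec(1, base(F9 = 0.15, F84 = 0.12, F70 = 0.08)),
    class_spec(1, base(F1 = 0.15, F60 = 0.10)),
    class_spec(1, base()),
    class_spec(1, base(F3 = 0.15, F4 = 0.12)),
    class_spec(1, base(F50 = 0.15, F3 = 0.10))
  )[seq_len(n_classes)]
  w <- rep(1 / n_classes, n_classes)
  for (i in seq_len(n_classes)) specs[[i]]$weight <- w[i]
  names(specs) <- paste0("class", seq_len(n_classes))
  sim_config(n_cases = n_cases, n_controls_per_case = 1,
             latent_classes = specs, seed = seed, ...)
}
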