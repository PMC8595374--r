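#' Define a substitution/indel cost model over composite states
#'
#' The default `paper_overlap` scheme prices the substitution of one
#' cumulative diagnosis set for another by their Sorensen-Dice
#' dissimilarity, `1 - 2|intersect(a,b)| / (|a| + |b|)` (0 when both are
#' empty): singleton-to-disjoint-singleton costs 1, and two two-category
#' states sharing one category cost 0.5. The `jaccard` scheme uses the
#' set-theoretic Jaccard distance `1 - |intersect(a,b)| / |union(a,b)|`,
#' and `constant`
#' prices every non-identical substitution at 1. Insertions and deletions
#' cost `indel_cost` each.
#'
#' @param scheme one of `"paper_overlap"`, `"jaccard"`, `"constant"`
#' @param indel_cost nonnegative indel cost (default 1, the unit cost)
#' @return an object of class `cost_model`
#' @export
cost_model <- function(scheme = c("paper_overlap", "jaccard", "constant"),
                       indel_cost = 1.0) {
  scheme <- match.arg(scheme)
  if (!is.numeric(indel_cost) || indel_cost < 0)
    stop("indel_cost must be nonnegative")
  structure(list(scheme = scheme, indel_cost = indel_cost),
            class = "cost_model")
}

#' Substitution cost between two composite states
#'
#' Vectorized over pairs of state bitmasks (recycled as usual).
#'
#' @param a,b integer state bitmasks
#' @param model a [cost_model()]
#' @param alphabet optional [build_alphabet()]; when given, states are
#'   checked to lie inside it
#' @return numeric vector of costs in `[0, 1]`
#' @examples
#' al <- build_alphabet(c("F1", "F3", "F4", "F5"))
#' m <- cost_model()
#' substitution_cost(state_unlabel("F1+F3", al$categories),
#'                   state_unlabel("F3+F4", al$categories), m)  # 0.5
#' @export
substitution_cost <- function(a, b, model = cost_model(), alphabet = NULL) {
  if (!is.null(alphabet)) {
    if (!all(a %in% alphabet$states) || !all(b %in% alphabet$states))
      stop("state outside the alphabet")
  }
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 0) || any(b < 0)) stop("state bitmasks must be nonnegative")
  switch(model$scheme,
    constant = as.numeric(a != b),
    jaccard = {
      inter <- popcount(bitwAnd(a, b))
      union <- popcount(bitwOr(a, b))
      ifelse(union == 0, 0, 1 - inter / union)
    },
    paper_overlap = {
      inter <- popcount(bitwAnd(a, b))
      tot <- popcount(a) + popcount(b)
      ifelse(tot == 0, 0, 1 - 2 * inter / tot)
    })
}

# dense cost matrix over a vector of state masks, dimnames = mask keys
cost_matrix <- function(states, model) {
  S <- length(states)
  m <- outer(states, states,
             function(a, b) substitution_cost(a, b, model))
  dimnames(m) <- list(as.character(states), as.character(states))
  m
}
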