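#' Build the composite-state alphabet over diagnosis categories
#'
#' A person's state at any time is the cumulative *set* of diagnosis
#' categories received so far. With `C` categories there are `2^C` possible
#' states: the empty "no diagnosis" state, `C` singletons, and
#' `2^C - C - 1` multi-category combinations (247 for the default eight
#' psychiatric categories). States are encoded as bitmasks, bit `i` set
#' when category `i` (in the order given) is present.
#'
#' @param categories character vector of unique category labels
#'   (1 to 16 of them). Defaults to the eight ICD-10 F-chapter groups
#'   used throughout the package.
#' @return an object of class `state_alphabet` with elements
#'   `categories`, `n_categories`, `states` (integer bitmasks `0:(2^C-1)`)
#'   and `labels` (a label per state, `"NONE"` for the empty set,
#'   `"+"`-joined category labels otherwise).
#' @examples
#' a <- build_alphabet(c("F1", "F3", "F4"))
#' length(a$states)   # 8
#' @export
build_alphabet <- function(categories = default_categories()) {
  categories <- as.character(categories)
  if (length(categories) < 1L || length(categories) > 16L)
    stop("between 1 and 16 categories are supported, got ", length(categories))
  if (anyDuplicated(categories))
    stop("duplicate category labels: ",
         paste(unique(categories[duplicated(categories)]), collapse = ", "))
  C <- length(categories)
  states <- 0:(2L^C - 1L)
  structure(
    list(categories = categories,
         n_categories = C,
         states = states,
         labels = state_label(states, categories)),
    class = "state_alphabet")
}

#' Default diagnosis category labels
#'
#' The eight comorbid psychiatric diagnosis groups (ICD-10 F-chapter
#' shorthand): substance use (F1), mood (F3), neurotic/anxiety (F4),
#' eating (F50), personality (F60), intellectual disability (F70),
#' pervasive developmental (F84) and childhood behavioural (F9)
#' disorders.
#'
#' @return character vector of length 8
#' @export
default_categories <- function() {
  c("F1", "F3", "F4", "F50", "F60", "F70", "F84", "F9")
}

#' @export
print.state_alphabet <- function(x, ...) {
  cat("State alphabet:", x$n_categories, "categories,",
      length(x$states), "states\n")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

# number of set bits of each (small, < 2^16) integer
popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Human-readable label of a state bitmask
#'
#' @param state integer vector of bitmasks
#' @param categories category labels defining bit order
#' @return character vector; `"NONE"` for the empty state, otherwise
#'   category labels joined with `"+"` in alphabet order
#' @export
state_label <- function(state, categories) {
  vapply(state, function(s) {
    if (s == 0L) return("NONE")
    paste(categories[bitwAnd(s, bitwShiftL(1L, seq_along(categories) - 1L)) != 0L],
          collapse = "+")
  }, character(1))
}

#' Parse a state label back to its bitmask
#'
#' Inverse of [state_label()].
#'
#' @param label character vector of `"+"`-joined labels (`"NONE"` = empty set)
#' @param categories category labels defining bit order
#' @return integer vector of bitmasks
#' @export
state_unlabel <- function(label, categories) {
  vapply(label, function(l) {
    if (identical(l, "NONE") || l == "") return(0L)
    parts <- strsplit(l, "+", fixed = TRUE)[[1]]
    idx <- match(parts, categories)
    if (anyNA(idx)) stop("unknown category in state label '", l, "'")
    as.integer(sum(bitwShiftL(1L, idx - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

# bitmask for a set of category labels
categories_to_mask <- function(cats, categories) {
  if (length(cats) == 0L) return(0L)
  idx <- match(cats, categories)
  if (anyNA(idx)) stop("unknown category: ", paste(cats[is.na(idx)], collapse = ", "))
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}
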