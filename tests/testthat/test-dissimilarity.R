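cats5 <- c("F1", "F3", "F4", "F5", "F6")
al5 <- build_alphabet(cats5)
st <- function(lab) state_unlabel(lab, cats5)

test_that("set-overlap substitution costs reproduce the worked examples", {
  m <- cost_model("paper_overlap")
  expect_equal(substitution_cost(st("F1"), st("F3"), m), 1)
  expect_equal(substitution_cost(st("F1+F3"), st("F3+F4"), m), 0.5)
  expect_equal(substitution_cost(st("F1+F3"), st("F4+F5"), m), 1)
  expect_equal(substitution_cost(st("F1+F3"), st("F1+F3"), m), 0)
  expect_equal(substitution_cost(0L, 0L, m), 0)
})

test_that("cost schemes are symmetric, zero on the diagonal, bounded", {
  for (scheme in c("paper_overlap", "jaccard", "constant")) {
    m <- cost_model(scheme)
    states <- al5$states
    cm <- outer(states, states, function(a, b) substitution_cost(a, b, m))
    expect_equal(cm, t(cm))
    expect_true(all(diag(cm) == 0))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  # the two set-overlap schemes disagree exactly where partial overlap occurs
  expect_equal(substitution_cost(st("F1+F3"), st("F3+F4"),
                                 cost_model("jaccard")), 2 / 3)
  expect_error(cost_model(indel_cost = -1), "nonnegative")
  expect_error(substitution_cost(512L, 0L, cost_model(),
                                 alphabet = al5), "outside")
})

test_that("transition estimation pools counts over persons and intervals", {
  f1 <- 1L
  s1 <- make_seq(c(0L, 0L, f1))
  s2 <- make_seq(c(0L, 0L, 0L), id = "S2")
  tm <- estimate_transitions(list(s1, s2))
  expect_equal(tm$estimated_from, 4L)
  expect_equal(tm$P["0", "0"], 3 / 4)
  expect_equal(tm$P["0", "1"], 1 / 4)
  expect_equal(unname(rowSums(tm$P)), rep(1, nrow(tm$P)))
  # states never observed as origins get a self-loop row
  expect_equal(tm$P["1", "1"], 1)
  # all-constant sequences give identity rows
  tm0 <- estimate_transitions(list(make_seq(c(0L, 0L)), make_seq(c(0L, 0L))))
  expect_equal(tm0$P, matrix(1, 1, 1, dimnames = list("0", "0")))
  expect_error(estimate_transitions(list(make_seq(0L))), "transition")
})

test_that("tail imputation propagates the chain to the target length", {
  # identity chain: every imputed interval is a point mass at the last state
  s <- make_seq(c(0L, 1L), target_length = 5L)
  tm_id <- structure(list(P = diag(2), states = c(0L, 1L),
                          estimated_from = 1L), class = "transition_model")
  dimnames(tm_id$P) <- list(c("0", "1"), c("0", "1"))
  tail <- impute_tail(s, tm_id)
  expect_equal(nrow(tail), 3L)
  expect_true(all(tail[, "1"] == 1))

  # fully observed: empty tail
  expect_equal(nrow(impute_tail(make_seq(c(0L, 1L)), tm_id)), 0L)

  # two-step absorbing chain: 0.9/0.1 then 0.81/0.19
  P <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  tm <- structure(list(P = P, states = c(0L, 1L), estimated_from = 10L),
                  class = "transition_model")
  tail2 <- impute_tail(make_seq(0L, target_length = 3L), tm)
  expect_equal(unname(tail2[1, ]), c(0.9, 0.1))
  expect_equal(unname(tail2[2, ]), c(0.81, 0.19))

  # alphabet mismatch: last observed state unknown to the model
  expect_error(impute_tail(make_seq(3L, target_length = 2L), tm),
               "not in the transition model")
})

test_that("position costs take expectations over censored states", {
  m <- cost_model()
  f1 <- st("F1"); f3 <- st("F3")
  # degenerate distribution = plain substitution cost
  point <- stats::setNames(1, as.character(f3))
  expect_equal(position_cost(f1, point, m),
               substitution_cost(f1, f3, m))
  # weighted mean: 0.5 on {F1}, 0.5 on {F3} vs observed {F1}
  half <- stats::setNames(c(0.5, 0.5), as.character(c(f1, f3)))
  expect_equal(position_cost(half, f1, m), 0.5)
  # identical distributions need not cost 0 (independent draws)
  expect_equal(position_cost(half, half, m), 0.5)
  expect_error(position_cost(stats::setNames(c(0.5, 0.6),
                                             as.character(c(f1, f3))),
                             f1, m), "not normalized")
})

test_that("om_distance solves small alignments exactly", {
  m <- cost_model()
  f1 <- st("F1"); f3 <- st("F3")
  expect_equal(om_distance(make_seq(c(0L, f1)), make_seq(c(0L, f1)), model = m), 0)
  # one substitution at position 2 is cheaper than two indels
  expect_equal(om_distance(make_seq(c(0L, f1)), make_seq(c(0L, f3)), model = m), 1)
  # indels when lengths differ
  expect_equal(om_distance(make_seq(c(0L, f1)), make_seq(0L), model = m), 1)
})

test_that("om_distance equals the exhaustive edit-script minimum", {
  # all monotone sequences of length <= 3 over a 2-category alphabet
  # (the full length-4 sweep runs in the acceptance suite)
  m <- cost_model()
  seqs <- unlist(lapply(1:3, monotone_sequences), recursive = FALSE)
  for (a in seqs) for (b in seqs) {
    got <- om_distance(make_seq(a), make_seq(b, id = "S2"), model = m)
    expect_equal(got, om_oracle(a, b, m), tolerance = 1e-12)
  }
})

test_that("imputation-length bookkeeping is enforced", {
  tm_id <- structure(list(P = diag(2), states = c(0L, 1L),
                          estimated_from = 1L), class = "transition_model")
  dimnames(tm_id$P) <- list(c("0", "1"), c("0", "1"))
  s5 <- make_seq(c(0L, 1L), target_length = 5L)
  s6 <- make_seq(c(0L, 1L), target_length = 6L, id = "S2")
  expect_error(om_distance(s5, s6, impute_tail(s5, tm_id),
                           impute_tail(s6, tm_id)),
               "length mismatch")
  expect_error(om_distance(s5, s6, impute_tail(s6, tm_id)[1:2, , drop = FALSE],
                           NULL), "not extended")
})

test_that("imputation makes distances length-independent in the deterministic limit", {
  # identical observed prefixes, different censoring; a deterministic
  # chain imputes identical tails, so the distance collapses to zero
  f1 <- 1L
  long <- make_seq(c(0L, 0L, f1, f1, f1, f1), target_length = 6L)
  short <- make_seq(c(0L, 0L, f1), target_length = 6L, id = "S2")
  tm_det <- structure(list(P = diag(2), states = c(0L, f1),
                           estimated_from = 1L), class = "transition_model")
  dimnames(tm_det$P) <- list(c("0", "1"), c("0", "1"))
  d <- om_distance(long, short, impute_tail(long, tm_det),
                   impute_tail(short, tm_det))
  expect_equal(d, 0)
})

test_that("the pairwise matrix is a well-behaved dissimilarity", {
  co <- simulate_cohort(sim_config(n_cases = 40, seed = 17))
  ss <- build_sequences(co)
  D <- pairwise_matrix(ss)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # triangle inequality over random triples
  set.seed(1)
  n <- nrow(D)
  for (r in 1:500) {
    ijk <- sample.int(n, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-9)
  }
  # identical sequences -> zero matrix
  ss2 <- make_seqset(list(make_seq(c(0L, 1L, 3L), id = "A"),
                          make_seq(c(0L, 1L, 3L), id = "B"),
                          make_seq(c(0L, 1L, 3L), id = "C")))
  expect_true(all(pairwise_matrix(ss2) == 0))
  # permuting the input permutes rows/columns consistently
  perm <- c(3, 1, 2)
  ss3 <- make_seqset(list(make_seq(c(0L, 0L, 1L), id = "A"),
                          make_seq(c(0L, 1L, 3L), id = "B"),
                          make_seq(c(0L, 0L, 0L), id = "C")))
  D3 <- pairwise_matrix(ss3)
  ssp <- make_seqset(ss3$sequences[perm])
  expect_equal(pairwise_matrix(ssp), D3[perm, perm])
})

test_that("increment sensitivity returns high correlations on finer grids", {
  co <- simulate_cohort(sim_config(n_cases = 30, seed = 19))
  r <- increment_sensitivity(co, increments = c(1, 0.5), target_years = 36)
  expect_length(r, 1L)
  expect_gte(r[["6m"]], 0.95)
  # the same increment twice correlates perfectly
  r1 <- increment_sensitivity(co, increments = c(1, 1), target_years = 36)
  expect_equal(unname(r1), 1)
  expect_error(increment_sensitivity(co, increments = 1), "at least one")
})
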