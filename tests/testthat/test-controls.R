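test_that("simulate_random matches lengths and degenerate distributions", {
  s <- simulate_random(c(5, 9), freq = c(0.5, 0.5), seed = 3)
  expect_identical(sequence_lengths(s), c(5L, 9L))
  expect_identical(vapply(s$sequences, `[[`, "", "group"),
                   c("random", "random"))

  s1 <- simulate_random(10, freq = c(1, 0, 0), seed = 3)
  expect_true(all(s1$sequences[[1]]$actions == 1L))
  expect_error(simulate_random(0, c(1)), "lengths")
  expect_error(simulate_random(5, c(0.6, 0.6)), "sum to 1")
  expect_error(simulate_random(5, c(1.2, -0.2)), "non-negative")
})

test_that("simulate_random recovers the target frequencies at n = 1e5", {
  freq <- c(0.3, 0.25, 0.15, 0.1, 0.08, 0.07, 0.05)
  s <- simulate_random(1e5, freq, seed = 42)
  expect_lt(max(abs(behavior_frequencies(s) - freq)), 0.01)
})

test_that("identical seeds reproduce identical sequences", {
  a <- simulate_random(c(20, 20), c(0.4, 0.6), seed = 11)
  b <- simulate_random(c(20, 20), c(0.4, 0.6), seed = 11)
  expect_identical(a$sequences[[1]]$actions, b$sequences[[1]]$actions)
  P <- transition_matrix(matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE))
  m1 <- simulate_markov(c(50, 50), P, c(0.5, 0.5), seed = 5)
  m2 <- simulate_markov(c(50, 50), P, c(0.5, 0.5), seed = 5)
  expect_identical(m1$sequences[[2]]$actions, m2$sequences[[2]]$actions)
})

test_that("fit_markov counts transitions within sequences only", {
  eth <- ethogram(c("a", "b"))
  set <- sequence_set(eth, list(
    action_seq("s", "i", "g", c(1, 2, 1, 2, 1, 2), eth)))
  P <- fit_markov(set)
  expect_equal(P$probs["a", "b"], 1)
  expect_equal(P$probs["b", "a"], 1)

  # "a a a": deterministic self-loop
  set2 <- sequence_set(eth, list(action_seq("s", "i", "g", c(1, 1, 1), eth)))
  expect_warning(P2 <- fit_markov(set2), "no outgoing")  # b never seen out
  expect_equal(P2$probs["a", "a"], 1)

  # boundary crossing would create an a->a transition here; there is none
  set3 <- sequence_set(eth, list(action_seq("s1", "i", "g", c(2, 1), eth),
                                 action_seq("s2", "i", "g", c(1, 2), eth)))
  P3 <- fit_markov(set3)
  expect_equal(P3$probs["a", "a"], 0)
})

test_that("final-only states get the marginal frequency row with a warning", {
  eth <- ethogram(c("a", "b", "c"))
  set <- sequence_set(eth, list(action_seq("s", "i", "g", c(1, 1, 3), eth)))
  expect_warning(P <- fit_markov(set), "marginal")
  marg <- unname(behavior_frequencies(set))
  expect_equal(unname(P$probs["c", ]), marg)
  expect_equal(unname(rowSums(P$probs)), rep(1, 3), tolerance = 1e-12)
})

test_that("fit_markov is consistent on shuffled uniform data", {
  set.seed(8)
  big <- sequence_set(ethogram(paste0("b", 1:7)),
                      list(action_seq("big", "i", "g",
                                      sample.int(7, 1e5, replace = TRUE))))
  P <- fit_markov(big)
  marg <- unname(behavior_frequencies(big))
  expect_lt(max(abs(sweep(P$probs, 2, marg))), 0.01)
})

test_that("check_ergodic classifies constructed chains", {
  id <- transition_matrix(diag(2))
  expect_identical(check_ergodic(id), list(irreducible = FALSE, aperiodic = TRUE))

  flip <- transition_matrix(matrix(c(0, 1, 1, 0), 2))
  expect_identical(check_ergodic(flip), list(irreducible = TRUE, aperiodic = FALSE))

  pos <- transition_matrix(matrix(0.25, 4, 4))
  expect_identical(check_ergodic(pos), list(irreducible = TRUE, aperiodic = TRUE))

  # 3-cycle: irreducible, period 3
  cyc <- transition_matrix(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE))
  expect_identical(check_ergodic(cyc), list(irreducible = TRUE, aperiodic = FALSE))

  # reducible with an aperiodic absorbing class
  red <- transition_matrix(matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE))
  expect_identical(check_ergodic(red), list(irreducible = FALSE, aperiodic = TRUE))
})

test_that("simulate_markov follows deterministic chains and length contract", {
  P <- transition_matrix(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  s <- simulate_markov(5, P, initial = c(1, 0), seed = 1)
  expect_identical(s$sequences[[1]]$actions, c(1L, 2L, 1L, 2L, 1L))
  expect_error(simulate_markov(0, P, c(1, 0)), "lengths")

  lens <- c(3, 17, 8)
  s2 <- simulate_markov(lens, P, c(0.5, 0.5), seed = 2)
  expect_identical(sequence_lengths(s2), as.integer(lens))
})

test_that("fit_markov recovers the generating matrix from a long chain", {
  probs <- matrix(c(
    0.50, 0.20, 0.10, 0.05, 0.05, 0.05, 0.05,
    0.10, 0.40, 0.20, 0.10, 0.10, 0.05, 0.05,
    0.05, 0.10, 0.50, 0.15, 0.10, 0.05, 0.05,
    0.10, 0.10, 0.10, 0.40, 0.10, 0.10, 0.10,
    0.05, 0.05, 0.05, 0.05, 0.60, 0.10, 0.10,
    0.20, 0.10, 0.10, 0.10, 0.10, 0.30, 0.10,
    0.15, 0.15, 0.14, 0.14, 0.14, 0.14, 0.14), 7, byrow = TRUE)
  P <- transition_matrix(probs)
  sim <- simulate_markov(1e5, P, initial = rep(1 / 7, 7), seed = 7)
  Phat <- fit_markov(sim)
  expect_lt(max(abs(Phat$probs - P$probs)), 0.02)
})

test_that("transition matrix CSV round-trips", {
  P <- transition_matrix(matrix(c(0.3, 0.7, 0.6, 0.4), 2, byrow = TRUE),
                         labels = c("x", "y"))
  f <- tempfile(fileext = ".csv")
  write_transition_matrix(P, f)
  back <- read_transition_matrix(f)
  expect_equal(back$probs, P$probs)
  expect_identical(back$labels, c("x", "y"))
})
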