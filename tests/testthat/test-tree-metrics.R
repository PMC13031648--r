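# grammars used across the encoding tests, built by hand in the package's
# symbol convention (positive terminal, negative rule reference)
manual_grammar <- function(start, rules) {
  structure(list(sequence_id = "manual", k = 2L, start = start,
                 rules = rules), class = "seq_grammar")
}

test_that("encode_rule is the recursive preorder 0/1 expansion", {
  g1 <- manual_grammar(c(-1L, -1L), list(`1` = c(1L, 2L)))
  expect_identical(encode_rule(g1, 1), "11")

  g2 <- manual_grammar(c(-2L, -2L),
                       list(`1` = c(1L, 1L), `2` = c(-1L, 2L)))
  expect_identical(encode_rule(g2, 2), "0111")

  g3 <- manual_grammar(c(-3L, -3L),
                       list(`1` = c(1L, 2L), `3` = c(-1L, -1L)))
  expect_identical(encode_rule(g3, 3), "011011")
  expect_error(encode_rule(g3, 99), "unknown rule")
})

test_that("nesting depth follows the recursive definition", {
  g2 <- manual_grammar(c(-2L, -2L),
                       list(`1` = c(1L, 1L), `2` = c(-1L, 2L)))
  expect_identical(nesting_depth(g2, symbol = 1L), 0L)  # terminal
  expect_identical(nesting_depth(g2, rule_id = 1), 1L)
  expect_identical(nesting_depth(g2, rule_id = 2), 2L)
})

test_that("chunks and phrase length on the worked examples", {
  g <- induce_grammar(c(1, 2, 4, 3, 1, 2))
  expect_identical(chunks(g), 1L)
  expect_identical(phrase_length(g, 1), 2L)

  g8 <- induce_grammar(rep(c(1L, 2L), 4))
  expect_identical(chunks(g8), 2L)
  expect_identical(phrase_length(g8, 2), 4L)  # expands to a b a b

  # one chunk embedded inside a 3-action phrase
  g3 <- manual_grammar(c(-2L, -2L), list(`1` = c(2L, 7L), `2` = c(-1L, 2L)))
  expect_identical(phrase_length(g3, 2), 3L)
})

test_that("entropy, gini and tnt match their frozen hand-derived values", {
  expect_equal(structural_entropy("11"), 0)
  expect_equal(structural_entropy("0111"), 0.811278, tolerance = 1e-6)
  expect_equal(structural_entropy("01"), 1)
  expect_equal(gini_bits("11"), 0)
  expect_equal(gini_bits("0111"), 0)
  expect_equal(gini_bits("011011"), 0.3)
  expect_equal(tnt_ratio("11"), 0)
  expect_equal(tnt_ratio("0111"), 1 / 3)
  expect_equal(tnt_ratio("011011"), 0.5)
  expect_error(structural_entropy(""), "non-empty")
  expect_error(gini_bits("012"), "only 0 and 1")
  expect_error(tnt_ratio("00"), "no terminal")
})

test_that("bit metrics agree with brute-force formula evaluation, all strings <= 8", {
  for (b in all_bitstrings(8)) {
    expect_equal(structural_entropy(b), oracle_entropy(b), tolerance = 1e-12)
    expect_equal(gini_bits(b), oracle_gini(b), tolerance = 1e-12)
    if (grepl("1", b)) {
      expect_equal(tnt_ratio(b), oracle_tnt(b), tolerance = 1e-12)
    }
  }
})

test_that("phrase length and nesting cross-check against encodings and expansion", {
  for (s in random_grammar_sequences(150, seed = 2024)) {
    g <- induce_grammar(s)
    if (chunks(g) == 0) next
    depths <- oracle_depths(g)
    for (id in names(g$rules)) {
      bits <- encode_rule(g, as.integer(id))
      n1 <- sum(strsplit(bits, "")[[1]] == "1")
      expect_identical(phrase_length(g, as.integer(id)),
                       length(oracle_expand_rule(g, id)))
      expect_identical(phrase_length(g, as.integer(id)), as.integer(n1))
      expect_identical(nesting_depth(g, rule_id = as.integer(id)),
                       as.integer(depths[[id]]))
      # valid rule encodings always have fewer 0s than 1s
      n0 <- nchar(bits) - n1
      expect_lt(n0, n1)
      expect_lt(structural_entropy(bits), 1)
      expect_lt(tnt_ratio(bits), 1)
    }
  }
})

test_that("sequence_metrics composes the per-rule measures", {
  m0 <- sequence_metrics(induce_grammar(1:5))
  expect_identical(m0$chunks, 0L)
  expect_identical(m0$max_nesting, 0L)
  expect_identical(nrow(m0$per_rule), 0L)

  m1 <- sequence_metrics(induce_grammar(c(1, 2, 4, 3, 1, 2)), group = "g")
  expect_identical(m1$chunks, 1L)
  expect_identical(m1$max_nesting, 1L)
  expect_equal(m1$per_rule$phrase_length, 2L)
  expect_equal(m1$per_rule$entropy, 0)
  expect_equal(m1$per_rule$gini, 0)
  expect_equal(m1$per_rule$tnt_ratio, 0)

  m2 <- sequence_metrics(induce_grammar(rep(c(1L, 2L), 4)))
  expect_identical(m2$chunks, 2L)
  expect_identical(m2$max_nesting, 2L)
  # chunks equals rows of per_rule, max_nesting the per-rule maximum
  expect_identical(m2$chunks, nrow(m2$per_rule))
  expect_identical(m2$max_nesting, max(m2$per_rule$nesting))
})

test_that("entropy = 0 iff gini = 0 and tnt = 0 iff no embedded rule", {
  for (s in random_grammar_sequences(60, seed = 31)) {
    g <- induce_grammar(s)
    m <- sequence_metrics(g)
    if (m$chunks == 0) next
    flat <- m$per_rule$nesting == 1  # no embedded rule
    expect_identical(m$per_rule$entropy == 0, flat)
    expect_identical(m$per_rule$tnt_ratio == 0, flat)
    expect_true(all(m$per_rule$gini[flat] == 0))
  }
})
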