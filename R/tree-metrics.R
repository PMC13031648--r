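#' Binary tree-shape encoding of a grammar rule
#'
#' Renders a rule as a string over {0,1} by recursive preorder expansion of
#' its right-hand side, left to right: a terminal emits `"1"`; an embedded
#' rule emits `"0"` followed by the encoding of its own right-hand side.
#' The rule's own root emits nothing, so a rule embedding no other rule
#' encodes as all 1s. The count of 1s equals the rule's phrase length
#' (terminal yield) and the count of 0s the number of embedded rule nodes.
#'
#' @param grammar a `seq_grammar`.
#' @param rule_id integer rule id (as in `names(grammar$rules)`).
#' @return single string over `{"0","1"}`.
#' @examples
#' g <- induce_grammar(rep(c(1, 2), 4))  # R2 -> R1 R1, R1 -> 1 2
#' encode_rule(g, 2)  # "011011"
#' @export
encode_rule <- function(grammar, rule_id) {
  rhs <- grammar$rules[[as.character(rule_id)]]
  if (is.null(rhs)) stop("unknown rule id: ", rule_id)
  rec <- function(syms) {
    unlist(lapply(syms, function(s) {
      if (s > 0) "1" else c("0", rec(grammar$rules[[as.character(-s)]]))
    }))
  }
  paste(rec(rhs), collapse = "")
}

#' Nesting depth of a grammar symbol
#'
#' Maximum depth of rule embedding: terminals have depth 0; a rule has
#' depth 1 plus the maximum depth over the symbols of its right-hand side.
#'
#' @param grammar a `seq_grammar`.
#' @param symbol a single symbol in grammar convention (positive terminal
#'   code or negative rule reference `-id`), or a rule id given as
#'   `rule_id`.
#' @param rule_id convenience: positive rule id, equivalent to
#'   `symbol = -rule_id`.
#' @return integer depth >= 0.
#' @export
nesting_depth <- function(grammar, symbol = NULL, rule_id = NULL) {
  if (is.null(symbol)) {
    if (is.null(rule_id)) stop("supply symbol or rule_id")
    symbol <- -as.integer(rule_id)
  }
  rec <- function(s, depth) {
    if (depth > length(grammar$rules) + 1L) stop("cyclic rule references")
    if (s > 0) return(0L)
    rhs <- grammar$rules[[as.character(-s)]]
    if (is.null(rhs)) stop("unknown rule id: ", -s)
    1L + max(vapply(rhs, rec, integer(1), depth = depth + 1L))
  }
  rec(as.integer(symbol), 0L)
}

#' Number of chunks (rules) in a grammar
#'
#' Counts the rules in the rule book; the start sequence R0 is not a rule.
#'
#' @param grammar a `seq_grammar`.
#' @return integer >= 0.
#' @export
chunks <- function(grammar) length(grammar$rules)

#' Phrase length (terminal yield) of a rule
#'
#' Number of terminal actions the rule expands to; always >= 2 since rules
#' are built from digrams, and equal to the count of 1s in
#' [encode_rule()].
#'
#' @inheritParams encode_rule
#' @return integer >= 2.
#' @export
phrase_length <- function(grammar, rule_id) {
  rhs <- grammar$rules[[as.character(rule_id)]]
  if (is.null(rhs)) stop("unknown rule id: ", rule_id)
  length(expand_grammar(grammar, rhs))
}

#' Structural entropy of a binary tree encoding
#'
#' Binary Shannon entropy (log base 2) of the 0/1 composition of the
#' encoding: `H = -(p0 log2 p0 + p1 log2 p1)` with `0 log 0 = 0`. Zero for
#' a rule embedding no other rule (all 1s); under the recursive encoding
#' the count of 0s is strictly below the count of 1s, so `H < 1`.
#'
#' @param bits non-empty string over `{"0","1"}` (or a vector of them,
#'   vectorized).
#' @return numeric in `[0, 1]`.
#' @export
structural_entropy <- function(bits) {
  vapply(bits, function(b) {
    cnt <- .count_bits(b)
    p <- cnt / sum(cnt)
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Gini coefficient of non-terminal positions
#'
#' Pairwise-dispersion statistic over the 1-based positions of 0s in the
#' encoding: `G = sum_i sum_j |x_i - x_j| / (2 m^2 mu)`, where `x` are the
#' sorted positions of 0s, `m` their number and `mu` their mean. Defined as
#' 0 when `m <= 1` (the formula is degenerate there; the zero-inflated
#' outcome model absorbs the point mass).
#'
#' @inheritParams structural_entropy
#' @return numeric in `[0, 1)`.
#' @export
gini_bits <- function(bits) {
  vapply(bits, function(b) {
    .check_bits(b)
    x <- which(strsplit(b, "")[[1]] == "0")
    m <- length(x)
    if (m <= 1) return(0)
    sum(abs(outer(x, x, "-"))) / (2 * m^2 * mean(x))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Terminal to non-terminal ratio
#'
#' Count of 0s (non-terminal nodes) divided by count of 1s (terminal
#' nodes), exactly as conventionally printed with the non-terminals in the
#' numerator; also called the node:leaf ratio. Strictly below 1 for valid
#' rule encodings.
#'
#' @inheritParams structural_entropy
#' @return numeric >= 0.
#' @export
tnt_ratio <- function(bits) {
  vapply(bits, function(b) {
    cnt <- .count_bits(b)
    if (cnt["n1"] == 0) stop("encoding contains no terminal (1) bits")
    unname(cnt["n0"] / cnt["n1"])
  }, numeric(1), USE.NAMES = FALSE)
}

.check_bits <- function(b) {
  if (!is.character(b) || length(b) != 1 || !nzchar(b)) {
    stop("bits must be a non-empty binary string")
  }
  if (grepl("[^01]", b)) stop("bits must contain only 0 and 1")
  invisible(TRUE)
}

.count_bits <- function(b) {
  .check_bits(b)
  chars <- strsplit(b, "")[[1]]
  c(n0 = sum(chars == "0"), n1 = sum(chars == "1"))
}

#' All six complexity measures for one grammar
#'
#' Per-sequence measures: `chunks` (rule count) and `max_nesting` (maximum
#' nesting depth over rules, 0 when the grammar has no rules). Per-rule
#' measures: nesting depth, phrase length, structural entropy, Gini
#' coefficient and terminal:non-terminal ratio, computed from each rule's
#' binary encoding.
#'
#' @param grammar a `seq_grammar`.
#' @param group optional group label copied onto the per-rule table.
#' @return list of class `sequence_metrics` with `sequence_id`, `chunks`,
#'   `max_nesting`, and `per_rule` (data.frame with one row per rule:
#'   `sequence_id, group, rule_id, bits, nesting, phrase_length, entropy,
#'   gini, tnt_ratio`).
#' @export
sequence_metrics <- function(grammar, group = "") {
  ids <- as.integer(names(grammar$rules))
  if (length(ids) == 0) {
    per_rule <- data.frame(sequence_id = character(), group = character(),
                           rule_id = integer(), bits = character(),
                           nesting = integer(), phrase_length = integer(),
                           entropy = numeric(), gini = numeric(),
                           tnt_ratio = numeric(), stringsAsFactors = FALSE)
    return(structure(list(sequence_id = grammar$sequence_id, chunks = 0L,
                          max_nesting = 0L, per_rule = per_rule),
                     class = "sequence_metrics"))
  }
  bits <- vapply(ids, function(i) encode_rule(grammar, i), character(1))
  nest <- vapply(ids, function(i) nesting_depth(grammar, rule_id = i), integer(1))
  pl <- vapply(ids, function(i) phrase_length(grammar, i), integer(1))
  per_rule <- data.frame(sequence_id = grammar$sequence_id, group = group,
                         rule_id = ids, bits = bits, nesting = nest,
                         phrase_length = pl,
                         entropy = structural_entropy(bits),
                         gini = gini_bits(bits),
                         tnt_ratio = tnt_ratio(bits),
                         stringsAsFactors = FALSE)
  structure(list(sequence_id = grammar$sequence_id, chunks = length(ids),
                 max_nesting = max(nest), per_rule = per_rule),
            class = "sequence_metrics")
}

#' @export
print.sequence_metrics <- function(x, ...) {
  cat("<sequence_metrics ", x$sequence_id, "> chunks=", x$chunks,
      " max_nesting=", x$max_nesting, "\n", sep = "")
  if (nrow(x$per_rule)) print(x$per_rule[, -(1:2)], row.names = FALSE)
  invisible(x)
}

#' Metrics tables for a whole sequence set
#'
#' Runs [induce_grammar()] and [sequence_metrics()] over every sequence of
#' a set and stacks the results.
#'
#' @param set a [sequence_set()].
#' @param k Sequitur digram-promotion threshold (default 2).
#' @return list with `rules` (per-rule metrics table, one row per rule
#'   across all sequences) and `sequences` (per-sequence summary:
#'   `sequence_id, group, length, compressed_length, chunks, max_nesting`).
#' @export
set_metrics <- function(set, k = 2L) {
  stopifnot(inherits(set, "seq_set"))
  rule_tabs <- vector("list", length(set$sequences))
  seq_rows <- vector("list", length(set$sequences))
  for (i in seq_along(set$sequences)) {
    s <- set$sequences[[i]]
    g <- induce_grammar(s$actions, k = k, sequence_id = s$sequence_id)
    m <- sequence_metrics(g, group = s$group)
    rule_tabs[[i]] <- m$per_rule
    seq_rows[[i]] <- data.frame(sequence_id = s$sequence_id, group = s$group,
                                length = length(s$actions),
                                compressed_length = compressed_length(g),
                                chunks = m$chunks,
                                max_nesting = m$max_nesting,
                                stringsAsFactors = FALSE)
  }
  list(rules = do.call(rbind, rule_tabs), sequences = do.call(rbind, seq_rows))
}
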