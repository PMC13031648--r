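# Independent brute-force oracles and tiny fixtures shared across tests.

# literal transcription of the complexity formulas, loop style, kept
# deliberately separate from the package implementations
oracle_entropy <- function(bits) {
  ch <- strsplit(bits, "")[[1]]
  N <- length(ch)
  n0 <- 0; n1 <- 0
  for (c in ch) if (c == "0") n0 <- n0 + 1 else n1 <- n1 + 1
  h <- 0
  for (cnt in c(n0, n1)) {
    p <- cnt / N
    if (p > 0) h <- h - p * log(p, base = 2)
  }
  h
}

oracle_gini <- function(bits) {
  ch <- strsplit(bits, "")[[1]]
  x <- integer(0)
  for (i in seq_along(ch)) if (ch[i] == "0") x <- c(x, i)
  m <- length(x)
  if (m <= 1) return(0)
  total <- 0
  for (i in 1:m) for (j in 1:m) total <- total + abs(x[i] - x[j])
  total / (2 * m^2 * mean(x))
}

oracle_tnt <- function(bits) {
  ch <- strsplit(bits, "")[[1]]
  sum(ch == "0") / sum(ch == "1")
}

# iterative (non-recursive) expansion of one rule's RHS to terminals
oracle_expand_rule <- function(grammar, rule_id) {
  syms <- grammar$rules[[as.character(rule_id)]]
  for (pass in 1:(length(grammar$rules) + 1)) {
    if (all(syms > 0)) return(syms)
    out <- integer(0)
    for (s in syms) {
      if (s > 0) out <- c(out, s)
      else out <- c(out, grammar$rules[[as.character(-s)]])
    }
    syms <- out
  }
  stop("expansion did not terminate")
}

# depth by fixed-point iteration over the rule book
oracle_depths <- function(grammar) {
  ids <- names(grammar$rules)
  d <- setNames(rep(1L, length(ids)), ids)
  repeat {
    d_new <- d
    for (id in ids) {
      rhs <- grammar$rules[[id]]
      child <- vapply(rhs, function(s) if (s > 0) 0L else d[[as.character(-s)]],
                      integer(1))
      d_new[[id]] <- 1L + max(child)
    }
    if (identical(d_new, d)) return(d)
    d <- d_new
  }
}

all_bitstrings <- function(max_len) {
  out <- character(0)
  for (n in 1:max_len) {
    grid <- expand.grid(rep(list(c("0", "1")), n), stringsAsFactors = FALSE)
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

toy_csv <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  path
}

# a deterministic small observed-like set for IO and control tests
toy_set <- function() {
  eth <- ethogram(c("gather", "strike", "grip", "reposition",
                    "hand", "shell", "eat"))
  seqs <- list(
    action_seq("s1", "ind1", "chimpanzee", c(1, 2, 2, 4, 2, 6, 7, 1, 2, 2), eth),
    action_seq("s2", "ind1", "chimpanzee", c(1, 2, 4, 2, 2, 6, 7, 1, 2, 4, 2, 2), eth),
    action_seq("s3", "ind2", "chimpanzee", c(2, 2, 2, 6, 7), eth))
  sequence_set(eth, seqs, "toy")
}

random_grammar_sequences <- function(n, seed, min_len = 5, max_len = 120) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sample.int(sample(2:7, 1), sample(min_len:max_len, 1), replace = TRUE)
  })
}
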