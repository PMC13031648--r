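#' Induce a Sequitur grammar from an action sequence
#'
#' Compresses a linear sequence of behavior codes into a context-free
#' grammar: a start sequence (R0) plus a rule book, where each rule stands
#' for a repeated digram (or nested composition of digrams). The algorithm
#' reads the sequence left to right; with `k = 2` it enforces the classical
#' Sequitur constraints — digram uniqueness (no adjacent symbol pair occurs
#' more than once across the grammar) and rule utility (every rule is used
#' at least twice). For `k > 2` a digram is promoted to a rule only at its
#' k-th (non-overlapping) occurrence and rules used fewer than k times are
#' inlined.
#'
#' @param actions integer vector of behavior codes (length >= 1), or an
#'   [action_seq()].
#' @param k digram-promotion threshold, >= 2 (default 2).
#' @param sequence_id identifier stored on the grammar (taken from the
#'   `action_seq` when one is supplied).
#' @return An object of class `seq_grammar`: list with `sequence_id`, `k`,
#'   `start` (integer vector; positive entries are terminal codes, negative
#'   entries `-i` reference rule `i`) and `rules` (named list of such
#'   vectors, ids `"1".."n"` in order of creation).
#' @examples
#' g <- induce_grammar(c(1, 2, 4, 3, 1, 2))  # "a b d c a b"
#' compressed_length(g)  # 4: R1 d c R1
#' expand_grammar(g)
#' @export
induce_grammar <- function(actions, k = 2L, sequence_id = "") {
  if (inherits(actions, "action_seq")) {
    if (!nzchar(sequence_id)) sequence_id <- actions$sequence_id
    actions <- actions$actions
  }
  actions <- as.integer(actions)
  if (length(actions) == 0) stop("cannot induce a grammar on an empty sequence")
  if (k < 2) stop("k must be >= 2")
  raw <- .sequitur_induce(actions, as.integer(k))
  structure(list(sequence_id = as.character(sequence_id), k = as.integer(k),
                 start = raw$start, rules = raw$rules),
            class = "seq_grammar")
}

#' @export
print.seq_grammar <- function(x, ...) {
  fmt <- function(v) paste(ifelse(v > 0, v, paste0("#", -v)), collapse = " ")
  cat("<seq_grammar", if (nzchar(x$sequence_id)) paste0(" ", x$sequence_id),
      "> k=", x$k, "\n  R0: ", fmt(x$start), "\n", sep = "")
  for (id in names(x$rules)) cat("  R", id, ": ", fmt(x$rules[[id]]), "\n", sep = "")
  invisible(x)
}

#' Expand a grammar back to its terminal sequence
#'
#' Recursively substitutes every rule reference by its right-hand side,
#' left to right, until only terminals remain. For any grammar returned by
#' [induce_grammar()] this reproduces the original sequence exactly.
#'
#' @param grammar a `seq_grammar`.
#' @param symbols internal: symbols to expand instead of `grammar$start`.
#' @return integer vector of behavior codes.
#' @export
expand_grammar <- function(grammar, symbols = grammar$start) {
  rules <- grammar$rules
  rec <- function(syms, depth) {
    if (depth > length(rules) + 1L) stop("cyclic rule references")
    out <- lapply(syms, function(s) {
      if (s > 0) return(s)
      rhs <- rules[[as.character(-s)]]
      if (is.null(rhs)) stop("dangling rule reference #", -s)
      rec(rhs, depth + 1L)
    })
    unlist(out)
  }
  as.integer(rec(symbols, 1L))
}

#' Number of symbols in the compressed start sequence
#'
#' @param grammar a `seq_grammar`.
#' @return integer: length of R0.
#' @export
compressed_length <- function(grammar) length(grammar$start)

#' Check grammar invariants by direct scan
#'
#' Verifies digram uniqueness (no ordered adjacent pair occurs more than
#' `k` - 1 ... i.e., more than once for k = 2, counting greedy
#' non-overlapping occurrences across R0 and all rule right-hand sides,
#' with occurrences matching a length-2 rule's own definition excluded),
#' rule utility (every rule referenced at least `k` times), minimum RHS
#' length 2, and acyclicity.
#'
#' @param grammar a `seq_grammar`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
validate_grammar <- function(grammar) {
  k <- grammar$k
  all_bodies <- c(list(`0` = grammar$start), grammar$rules)
  ids <- as.integer(names(grammar$rules))

  for (id in names(grammar$rules)) {
    if (length(grammar$rules[[id]]) < 2) stop("rule ", id, " has RHS shorter than 2")
  }

  # rule utility: reference counts
  refs <- stats::setNames(rep(0L, length(ids)), names(grammar$rules))
  for (body in all_bodies) {
    r <- -body[body < 0]
    if (length(r)) {
      tab <- table(r)
      refs[names(tab)] <- refs[names(tab)] + as.integer(tab)
    }
  }
  if (any(is.na(refs))) stop("dangling rule reference")
  low <- names(refs)[refs < k]
  if (length(low)) stop("rule utility violated for rule(s) ", paste(low, collapse = ","))

  # digram uniqueness (greedy non-overlapping count per digram)
  digram_count <- new.env(parent = emptyenv())
  bump <- function(key) {
    assign(key, (if (exists(key, envir = digram_count)) get(key, envir = digram_count) else 0L) + 1L,
           envir = digram_count)
  }
  defined <- vapply(grammar$rules, function(r) {
    if (length(r) == 2) paste(r, collapse = ",") else NA_character_
  }, character(1))
  for (nm in names(all_bodies)) {
    body <- all_bodies[[nm]]
    if (length(body) < 2) next
    last_end <- new.env(parent = emptyenv())
    i <- 1L
    while (i < length(body)) {
      key <- paste(body[i], body[i + 1L], collapse = ",", sep = ",")
      # skip the defining occurrence: a length-2 rule's own RHS
      is_def <- nm != "0" && !is.na(defined[nm]) && identical(defined[nm], key) &&
        length(body) == 2
      prev <- if (exists(key, envir = last_end)) get(key, envir = last_end) else -1L
      if (!is_def && i > prev) {  # non-overlapping with previous occurrence
        bump(key)
        assign(key, i + 1L, envir = last_end)
      }
      i <- i + 1L
    }
  }
  counts <- mget(ls(envir = digram_count), envir = digram_count)
  dup <- names(counts)[unlist(counts) >= k]
  if (length(dup)) {
    stop("digram uniqueness violated for digram(s) ", paste(dup, collapse = " | "))
  }

  # acyclicity via expansion with depth guard
  expand_grammar(grammar)
  invisible(TRUE)
}

#' Serialize / deserialize a grammar as rule-book JSON
#'
#' Schema: `{"sequence_id": "...", "k": 2, "start": ["#1","d","c","#1"],
#' "rules": {"1": ["a","b"]}}` — rule references are the rule id prefixed
#' `#`; terminals are behavior labels from the supplied ethogram.
#'
#' @param grammar a `seq_grammar`.
#' @param ethogram the [ethogram()] giving terminal labels.
#' @param path output / input JSON path.
#' @return `write_grammar_json()` returns `path` invisibly;
#'   `read_grammar_json()` returns a `seq_grammar`.
#' @export
write_grammar_json <- function(grammar, ethogram, path) {
  sym_str <- function(v) {
    vapply(v, function(s) if (s > 0) ethogram$labels[s] else paste0("#", -s),
           character(1))
  }
  obj <- list(sequence_id = grammar$sequence_id, k = grammar$k,
              start = sym_str(grammar$start),
              rules = lapply(grammar$rules, sym_str))
  if (length(obj$rules) == 0) obj$rules <- stats::setNames(list(), character(0))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(path)
}

#' @rdname write_grammar_json
#' @export
read_grammar_json <- function(path, ethogram) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  code <- stats::setNames(ethogram$codes, ethogram$labels)
  sym_int <- function(v) {
    v <- as.character(v)
    out <- integer(length(v))
    is_ref <- startsWith(v, "#")
    out[is_ref] <- -as.integer(sub("^#", "", v[is_ref]))
    out[!is_ref] <- unname(code[v[!is_ref]])
    if (anyNA(out)) stop("unknown symbol in grammar JSON: ",
                         v[is.na(out)][1])
    as.integer(out)
  }
  rules <- lapply(obj$rules, sym_int)
  structure(list(sequence_id = obj$sequence_id, k = as.integer(obj$k),
                 start = sym_int(obj$start),
                 rules = rules[order(as.integer(names(rules)))]),
            class = "seq_grammar")
}
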