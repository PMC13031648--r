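#' Simulate length-matched i.i.d. control sequences
#'
#' Draws one sequence per requested length, each action sampled
#' independently from `freq` — the "random" baseline: length-matched to the
#' observed data but with no sequential structure beyond the marginal
#' behavior frequencies.
#'
#' @param lengths integer vector of sequence lengths (all >= 1).
#' @param freq probability vector over behavior codes `1:length(freq)`
#'   (non-negative, summing to 1).
#' @param ethogram [ethogram()] for the output set; defaults to labels
#'   `b1..bK`.
#' @param seed integer seed; the draw is fully reproducible from it.
#' @param group group label on the generated sequences (default
#'   `"random"`).
#' @return A [sequence_set()] with one sequence per entry of `lengths`.
#' @export
simulate_random <- function(lengths, freq, ethogram = NULL, seed = 1L,
                            group = "random") {
  lengths <- as.integer(lengths)
  if (any(lengths < 1)) stop("all lengths must be >= 1")
  .check_prob(freq)
  if (is.null(ethogram)) ethogram <- ethogram(paste0("b", seq_along(freq)))
  stopifnot(length(freq) == length(ethogram$labels))
  seqs <- withr_seed(seed, {
    lapply(seq_along(lengths), function(i) {
      action_seq(sprintf("%s_%03d", group, i), "sim", group,
                 sample.int(length(freq), lengths[i], replace = TRUE,
                            prob = freq))
    })
  })
  sequence_set(ethogram, seqs, provenance = paste0("simulate_random seed=", seed))
}

#' Fit a first-order Markov transition matrix
#'
#' Maximum-likelihood estimate pooled over all sequences: `P[i, j]` is the
#' count of transitions i -> j divided by the count of transitions out of
#' i. Transitions never cross sequence boundaries. A state observed only as
#' a final action (no outgoing transitions) gets the pooled marginal
#' frequency vector as its row, with a warning.
#'
#' @param set a non-empty [sequence_set()].
#' @return An object of class `transition_matrix`: list with `states`
#'   (behavior codes), `labels`, and `probs` (row-stochastic matrix).
#' @export
fit_markov <- function(set) {
  stopifnot(inherits(set, "seq_set"), length(set$sequences) > 0)
  n_states <- length(set$ethogram$labels)
  counts <- matrix(0, n_states, n_states,
                   dimnames = list(set$ethogram$labels, set$ethogram$labels))
  for (s in set$sequences) {
    a <- s$actions
    if (length(a) < 2) next
    from <- a[-length(a)]; to <- a[-1]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  out <- sum(counts)
  if (out == 0) stop("no transitions observed (all sequences have length 1)")
  probs <- counts / rowSums(counts)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    marg <- behavior_frequencies(set)
    for (i in which(empty)) probs[i, ] <- marg
    warning("state(s) with no outgoing transitions given the marginal ",
            "frequency row: ",
            paste(set$ethogram$labels[empty], collapse = ", "))
  }
  structure(list(states = set$ethogram$codes, labels = set$ethogram$labels,
                 probs = probs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", length(x$states), " states\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Construct a transition matrix from a raw probability matrix
#' @param probs square row-stochastic matrix.
#' @param labels optional state labels (defaults to rownames or `b1..bK`).
#' @return a `transition_matrix`.
#' @export
transition_matrix <- function(probs, labels = NULL) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == ncol(probs))
  if (any(probs < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-12)) stop("rows must sum to 1")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(probs))) rownames(probs)
      else paste0("b", seq_len(nrow(probs)))
  }
  dimnames(probs) <- list(labels, labels)
  structure(list(states = seq_len(nrow(probs)), labels = labels,
                 probs = probs),
            class = "transition_matrix")
}

#' Irreducibility and aperiodicity of a Markov chain
#'
#' Irreducible: the directed graph of positive-probability transitions is
#' strongly connected. Aperiodic: every communicating class that contains a
#' cycle has period 1, where the period is the gcd of its cycle lengths
#' (computed by the standard breadth-first-level argument: the gcd of
#' `level(u) + 1 - level(v)` over the class's internal edges). Classes with
#' no cycle impose no period constraint.
#'
#' @param P a `transition_matrix`.
#' @return list with logical `irreducible` and `aperiodic`.
#' @export
check_ergodic <- function(P) {
  A <- P$probs > 0
  n <- nrow(A)
  reach <- function(from) {  # states reachable from `from` in >= 1 step
    seen <- logical(n)
    frontier <- which(A[from, ])
    while (length(frontier)) {
      new <- frontier[!seen[frontier]]
      seen[new] <- TRUE
      if (length(new) == 0) break
      frontier <- which(apply(A[new, , drop = FALSE], 2, any) & !seen)
    }
    seen
  }
  R <- t(vapply(seq_len(n), reach, logical(n)))
  irreducible <- all(R)

  gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)
  # communicating classes: i ~ j iff mutually reachable (i ~ i always)
  same <- (R & t(R)) | diag(TRUE, n)
  done <- logical(n)
  aperiodic <- TRUE
  for (i in seq_len(n)) {
    if (done[i]) next
    cls <- which(same[i, ])
    done[cls] <- TRUE
    Ac <- A[cls, cls, drop = FALSE]
    if (!any(Ac)) next  # no internal edge, no cycle
    m <- length(cls)
    lev <- rep(NA_integer_, m)
    lev[1] <- 0L
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(Ac[u, ])) {
          if (is.na(lev[v])) {
            lev[v] <- lev[u] + 1L
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    per <- 0L
    for (u in seq_len(m)) {
      if (is.na(lev[u])) next
      for (v in which(Ac[u, ])) {
        if (!is.na(lev[v])) per <- gcd2(per, lev[u] + 1L - lev[v])
      }
    }
    if (per != 0L && per != 1L) aperiodic <- FALSE
  }
  list(irreducible = irreducible, aperiodic = aperiodic)
}

#' Simulate first-order Markov control sequences
#'
#' One chain realization per requested length: the first state is drawn
#' from `initial`, each subsequent state from the transition row of the
#' current state.
#'
#' @param lengths integer vector of sequence lengths (all >= 1).
#' @param P a `transition_matrix`.
#' @param initial probability vector over states for the first action; the
#'   recommended choice is the empirical distribution of first actions in
#'   the training set (see [initial_distribution()]).
#' @param ethogram [ethogram()] for the output set; defaults to the
#'   matrix's state labels.
#' @param seed integer seed.
#' @param group group label (default `"markov"`).
#' @return A [sequence_set()].
#' @export
simulate_markov <- function(lengths, P, initial, ethogram = NULL, seed = 1L,
                            group = "markov") {
  lengths <- as.integer(lengths)
  if (any(lengths < 1)) stop("all lengths must be >= 1")
  .check_prob(initial)
  stopifnot(inherits(P, "transition_matrix"),
            length(initial) == nrow(P$probs))
  if (is.null(ethogram)) ethogram <- ethogram(P$labels)
  n_states <- nrow(P$probs)
  seqs <- withr_seed(seed, {
    lapply(seq_along(lengths), function(i) {
      L <- lengths[i]
      a <- integer(L)
      a[1] <- sample.int(n_states, 1, prob = initial)
      if (L > 1) {
        for (t in 2:L) a[t] <- sample.int(n_states, 1, prob = P$probs[a[t - 1], ])
      }
      action_seq(sprintf("%s_%03d", group, i), "sim", group, a)
    })
  })
  sequence_set(ethogram, seqs, provenance = paste0("simulate_markov seed=", seed))
}

#' Empirical distribution of first actions
#'
#' @param set a [sequence_set()].
#' @return probability vector over behavior codes.
#' @export
initial_distribution <- function(set) {
  firsts <- vapply(set$sequences, function(s) s$actions[1], integer(1))
  counts <- tabulate(firsts, nbins = length(set$ethogram$labels))
  stats::setNames(counts / sum(counts), set$ethogram$labels)
}

#' Serialize / read a transition matrix as CSV (labels as header/rownames)
#' @param P a `transition_matrix`.
#' @param path CSV path.
#' @export
write_transition_matrix <- function(P, path) {
  utils::write.csv(as.data.frame(P$probs), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  transition_matrix(as.matrix(df), labels = rownames(df))
}

.check_prob <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  invisible(TRUE)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
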