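#' Specification for planted-grammar synthetic sequences
#'
#' Describes a stated world for fixture generation: sequences over a small
#' alphabet in which nested motifs are planted amid i.i.d. background
#' actions. Each selected motif is planted at least twice per sequence,
#' because Sequitur with K = 2 cannot chunk a pattern that occurs once.
#' The default motifs are a plain bigram, a bigram repeated within a
#' 4-gram (yielding nesting depth 2 when rediscovered), and a depth-3
#' chain (an 8-gram of nested bigram repeats).
#'
#' @param alphabet_size number of behavior codes (default 7, matching a
#'   7-behavior ethogram).
#' @param motifs list of integer vectors (terminal expansions of the
#'   nested rule templates); every motif must have length >= 2 and use
#'   codes within the alphabet.
#' @param insert_rate probability in `[0, 1]` that each motif is planted
#'   (twice) in a given sequence, budget permitting (default 0.8).
#' @param background probability vector over the alphabet for background
#'   actions; default mildly non-uniform, mimicking the skewed behavior
#'   frequencies of real ethogram data.
#' @param lengths integer vector of total sequence lengths.
#' @param seed integer master seed.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(alphabet_size = 7L,
                         motifs = list(c(1L, 2L),
                                       c(3L, 4L, 3L, 4L),
                                       c(5L, 6L, 5L, 6L, 5L, 6L, 5L, 6L)),
                         insert_rate = 0.8,
                         background = NULL,
                         lengths = rep(40L, 10L),
                         seed = 1L) {
  if (is.null(background)) {
    w <- c(0.30, 0.25, 0.15, 0.10, 0.08, 0.07, 0.05)[seq_len(alphabet_size)]
    background <- w / sum(w)
  }
  stopifnot(length(background) == alphabet_size,
            insert_rate >= 0, insert_rate <= 1)
  for (m in motifs) {
    if (length(m) < 2) stop("motifs must expand to length >= 2")
    if (any(m < 1 | m > alphabet_size)) stop("motif uses codes outside the alphabet")
  }
  lengths <- as.integer(lengths)
  if (any(lengths < 1)) stop("lengths must be >= 1")
  longest <- max(vapply(motifs, length, integer(1)))
  if (2L * longest > max(lengths)) {
    stop("motif of length ", longest, " can never be planted twice in ",
         "sequences of at most ", max(lengths), " actions")
  }
  structure(list(alphabet_size = as.integer(alphabet_size), motifs = motifs,
                 insert_rate = insert_rate, background = background,
                 lengths = lengths, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate sequences with planted hierarchical structure
#'
#' Each sequence is a seeded interleaving of fully expanded motif
#' instances (each selected motif planted twice, kept contiguous) and
#' background i.i.d. actions, with total length exactly as requested. A
#' motif is only planted when two copies fit the remaining length budget.
#' With `insert_rate = 0` this reduces to [simulate_random()].
#'
#' @param spec a [planted_spec()].
#' @param group group label (default `"planted"`).
#' @param ethogram optional [ethogram()]; defaults to labels `b1..bK`.
#' @return A [sequence_set()].
#' @export
generate_planted <- function(spec, group = "planted", ethogram = NULL) {
  stopifnot(inherits(spec, "planted_spec"))
  if (is.null(ethogram)) {
    ethogram <- ethogram(paste0("b", seq_len(spec$alphabet_size)))
  }
  seqs <- withr_seed(spec$seed, {
    lapply(seq_along(spec$lengths), function(i) {
      L <- spec$lengths[i]
      budget <- L
      pieces <- list()
      for (m in spec$motifs) {
        if (2L * length(m) <= budget && stats::runif(1) < spec$insert_rate) {
          pieces <- c(pieces, list(m, m))
          budget <- budget - 2L * length(m)
        }
      }
      if (budget > 0) {
        bg <- sample.int(spec$alphabet_size, budget, replace = TRUE,
                         prob = spec$background)
        pieces <- c(pieces, as.list(bg))
      }
      actions <- unlist(pieces[sample.int(length(pieces))])
      action_seq(sprintf("%s_%03d", group, i), "sim", group, actions)
    })
  })
  sequence_set(ethogram, seqs,
               provenance = paste0("generate_planted seed=", spec$seed))
}

#' Generate the three-way fixture suite
#'
#' Mirrors the length-matched three-group design used to benchmark
#' hierarchical complexity: 140 sequences per set over a 7-symbol
#' alphabet, with one length multiset drawn once (log-normal, clipped to
#' 8-200 actions) and shared across (1) a planted-grammar set, (2) a
#' first-order Markov set simulated from a model fitted to the planted
#' set, and (3) a length-matched i.i.d. set drawn from the planted set's
#' pooled behavior frequencies.
#'
#' @param seed integer master seed; every stream derives from it.
#' @param n_sequences number of sequences per set (default 140).
#' @param insert_rate motif insertion rate for the planted set.
#' @return list with `planted`, `markov`, `iid` (each a
#'   [sequence_set()]), and `lengths`.
#' @export
generate_suite <- function(seed = 1L, n_sequences = 140L, insert_rate = 0.8) {
  sub <- withr_seed(seed, sample.int(2^30, 4))
  lengths <- withr_seed(sub[1], {
    pmin(pmax(round(stats::rlnorm(n_sequences, log(30), 0.6)), 8L), 200L)
  })
  eth <- ethogram(paste0("b", 1:7))
  pspec <- planted_spec(lengths = lengths, seed = sub[2],
                        insert_rate = insert_rate)
  planted <- generate_planted(pspec, ethogram = eth)
  P <- fit_markov(planted)
  markov <- simulate_markov(lengths, P, initial_distribution(planted),
                            ethogram = eth, seed = sub[3])
  iid <- simulate_random(lengths, behavior_frequencies(planted),
                         ethogram = eth, seed = sub[4], group = "iid")
  list(planted = planted, markov = markov, iid = iid, lengths = lengths)
}
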