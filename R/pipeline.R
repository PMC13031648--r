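#' Pipeline stage commands
#'
#' File-to-file wrappers tying the analysis stages together, mirroring the
#' command-line interface (see `inst/cli/hierseq.R`). All stages are
#' deterministic given their inputs and the master seed; stochastic stages
#' log the derived seed they used.
#'
#' @name pipeline
NULL

.log <- function(...) message("[hierseq] ", ...)

.read_input <- function(input, ethogram_path = NULL, column_map = NULL) {
  eth <- if (!is.null(ethogram_path)) read_ethogram(ethogram_path) else NULL
  read_sequences(input, ethogram = eth, column_map = column_map)
}

#' @describeIn pipeline Induce one rule-book JSON per sequence (after the
#'   minimum-length filter) plus a compressed-length table
#'   (`compressed_lengths.csv`).
#' @param input path to a sequence CSV (`sequence_id, subject_id, group,
#'   position, behavior`).
#' @param out_dir output directory (created if missing).
#' @param ethogram_path optional `code,label` CSV fixing the ethogram.
#' @param k Sequitur digram-promotion threshold (default 2).
#' @param min_length minimum sequence length kept (default 8).
#' @param column_map passed to [read_sequences()].
#' @return `cmd_compress()`: invisibly, the list of grammars.
#' @export
cmd_compress <- function(input, out_dir, ethogram_path = NULL, k = 2L,
                         min_length = 8L, column_map = NULL) {
  set <- .read_input(input, ethogram_path, column_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flt <- filter_min_length(set, min_length)
  .log("loaded ", length(set), " sequences; min-length ", min_length,
       " filter kept ", length(flt$kept), ", removed ", flt$n_removed)
  grammars <- lapply(flt$kept$sequences, function(s) {
    induce_grammar(s, k = k)
  })
  rows <- vector("list", length(grammars))
  for (i in seq_along(grammars)) {
    g <- grammars[[i]]
    write_grammar_json(g, flt$kept$ethogram,
                       file.path(out_dir, paste0("rulebook_", g$sequence_id, ".json")))
    rows[[i]] <- data.frame(sequence_id = g$sequence_id,
                            length = length(flt$kept$sequences[[i]]$actions),
                            compressed_length = compressed_length(g))
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "compressed_lengths.csv"),
                   row.names = FALSE)
  write_ethogram(flt$kept$ethogram, file.path(out_dir, "ethogram.csv"))
  invisible(grammars)
}

#' @describeIn pipeline Compute the per-rule and per-sequence metric
#'   tables (`rule_metrics.csv`, `sequence_metrics.csv`).
#' @return `cmd_metrics()`: invisibly, the [set_metrics()] list.
#' @export
cmd_metrics <- function(input, out_dir, ethogram_path = NULL, k = 2L,
                        min_length = 8L, column_map = NULL) {
  set <- .read_input(input, ethogram_path, column_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flt <- filter_min_length(set, min_length)
  .log("metrics on ", length(flt$kept), " sequences (",
       flt$n_removed, " below min length ", min_length, ")")
  m <- set_metrics(flt$kept, k = k)
  utils::write.csv(m$rules, file.path(out_dir, "rule_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(m$sequences, file.path(out_dir, "sequence_metrics.csv"),
                   row.names = FALSE)
  invisible(m)
}

#' @describeIn pipeline Fit the Markov model on the input set and write
#'   length-matched `markov.csv` and `random.csv` control sets plus the
#'   transition matrix (`transition_matrix.csv`).
#' @param seed master seed driving both simulators via derived streams.
#' @return `cmd_simulate()`: invisibly, list with the two simulated sets
#'   and the transition matrix.
#' @export
cmd_simulate <- function(input, out_dir, ethogram_path = NULL,
                         min_length = 1L, seed = 1L, column_map = NULL) {
  set <- .read_input(input, ethogram_path, column_map)
  flt <- filter_min_length(set, min_length)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lengths <- sequence_lengths(flt$kept)
  sub <- withr_seed(seed, sample.int(2^30, 2))
  .log("simulating ", length(lengths), " length-matched controls; ",
       "derived seeds markov=", sub[1], " random=", sub[2])
  P <- fit_markov(flt$kept)
  erg <- check_ergodic(P)
  if (!erg$irreducible || !erg$aperiodic) {
    warning("fitted Markov chain is ",
            if (!erg$irreducible) "reducible " else "",
            if (!erg$aperiodic) "periodic" else "")
  }
  markov <- simulate_markov(lengths, P, initial_distribution(flt$kept),
                            ethogram = flt$kept$ethogram, seed = sub[1])
  random <- simulate_random(lengths, behavior_frequencies(flt$kept),
                            ethogram = flt$kept$ethogram, seed = sub[2])
  write_sequences(markov, file.path(out_dir, "markov.csv"))
  write_sequences(random, file.path(out_dir, "random.csv"))
  write_transition_matrix(P, file.path(out_dir, "transition_matrix.csv"))
  invisible(list(markov = markov, random = random, transition = P))
}

#' @describeIn pipeline Build per-group structure inventories from a
#'   stacked rule-metrics table and classify the target group's structures
#'   as shared/unique (`inventory.csv`, `classification.csv`, and a
#'   labeled `rule_metrics_labeled.csv` for the target group).
#' @param rules_csv path to a stacked rule-metrics CSV (multiple groups).
#' @param target group whose structures are classified (default
#'   `"chimpanzee"`, falling back to the first group present).
#' @return `cmd_share()`: invisibly, list with inventories and the
#'   classification.
#' @export
cmd_share <- function(rules_csv, out_dir, target = "chimpanzee") {
  rules <- utils::read.csv(rules_csv, stringsAsFactors = FALSE,
                           colClasses = c(bits = "character"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- unique(rules$group)
  if (!target %in% groups) target <- groups[1]
  invs <- lapply(groups, function(g) {
    build_inventory(rules$bits[rules$group == g], g)
  })
  names(invs) <- groups
  inv_df <- do.call(rbind, lapply(invs, function(inv) {
    data.frame(group = inv$group, bits = names(inv$structures),
               count = unname(inv$structures))
  }))
  utils::write.csv(inv_df, file.path(out_dir, "inventory.csv"),
                   row.names = FALSE)
  cls <- classify_shared(invs[[target]], invs[names(invs) != target])
  write_classification(cls, target, file.path(out_dir, "classification.csv"))
  labeled <- label_rules(rules[rules$group == target, , drop = FALSE],
                         cls$shared, cls$unique)
  utils::write.csv(labeled, file.path(out_dir, "rule_metrics_labeled.csv"),
                   row.names = FALSE)
  .log(target, ": ", length(cls$shared), " shared / ", length(cls$unique),
       " unique structures out of ",
       length(invs[[target]]$structures), " distinct")
  invisible(list(inventories = invs, classification = cls, labeled = labeled))
}

#' @describeIn pipeline Fit the group-comparison models for each requested
#'   outcome and write `comparison.csv`.
#' @param sequences_csv per-sequence metrics CSV (for `chunks`,
#'   `max_nesting`).
#' @param outcomes outcomes to model; defaults to all six.
#' @param reference reference group (default `"chimpanzee"`, falling back
#'   to the first group present).
#' @param method `"mcmc"` or `"mle"`.
#' @param chains,iter,warmup sampler configuration.
#' @return `cmd_compare()`: invisibly, the comparison table.
#' @export
cmd_compare <- function(rules_csv, sequences_csv, out_dir,
                        outcomes = c("chunks", "max_nesting", "phrase_length",
                                     "entropy", "gini", "tnt_ratio"),
                        reference = "chimpanzee", method = "mcmc",
                        chains = 4L, iter = 2000L, warmup = 1000L,
                        seed = 1L) {
  rules <- utils::read.csv(rules_csv, stringsAsFactors = FALSE,
                           colClasses = c(bits = "character"))
  seqs <- utils::read.csv(sequences_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_seq <- c("chunks", "max_nesting")
  fits <- lapply(outcomes, function(oc) {
    data <- if (oc %in% per_seq) seqs else rules
    spec <- model_spec(oc, reference = reference, chains = chains,
                       iter = iter, warmup = warmup, seed = seed)
    .log("fitting ", spec$family, " model for ", oc, " (", method, ")")
    fit_group_model(data, spec, method = method)
  })
  report <- compare_report(fits)
  utils::write.csv(report, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  invisible(report)
}

#' @describeIn pipeline Write the three-way fixture suite
#'   (`planted.csv`, `markov.csv`, `iid.csv`) and a JSON manifest
#'   recording the generator settings and seed.
#' @param n_sequences sequences per fixture set.
#' @return `cmd_fixtures()`: invisibly, the [generate_suite()] list.
#' @export
cmd_fixtures <- function(out_dir, seed = 1L, n_sequences = 140L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- generate_suite(seed = seed, n_sequences = n_sequences)
  write_sequences(suite$planted, file.path(out_dir, "planted.csv"))
  write_sequences(suite$markov, file.path(out_dir, "markov.csv"))
  write_sequences(suite$iid, file.path(out_dir, "iid.csv"))
  jsonlite::write_json(list(seed = seed, n_sequences = n_sequences,
                            alphabet_size = 7,
                            lengths = suite$lengths),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  .log("fixture suite written to ", out_dir, " (seed ", seed, ")")
  invisible(suite)
}
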