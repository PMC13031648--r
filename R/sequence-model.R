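#' Construct an ethogram
#'
#' An ethogram is the fixed inventory of behavior categories used to code
#' sequences: a bijection between behavior labels and contiguous integer
#' codes starting at 1.
#'
#' @param labels character vector of unique, non-empty behavior names. Codes
#'   are assigned `1:length(labels)` in the order given.
#' @return An object of class `ethogram`: list with `labels` and `codes`.
#' @examples
#' eth <- ethogram(c("gather", "strike", "eat"))
#' eth$codes
#' @export
ethogram <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("an ethogram needs at least one behavior")
  if (anyNA(labels) || any(!nzchar(labels))) stop("behavior labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate behavior label: ", labels[duplicated(labels)][1])
  }
  structure(list(labels = labels, codes = seq_along(labels)),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", length(x$labels), " behaviors: ",
      paste0(x$codes, "=", x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.ethogram <- function(x) length(x$labels)

#' Construct a single action sequence
#'
#' @param sequence_id,subject_id identifiers (coerced to character).
#' @param group categorical label (e.g., `"chimpanzee"`, `"markov"`,
#'   `"random"`).
#' @param actions integer vector of behavior codes, length >= 1.
#' @param ethogram the [ethogram()] the codes refer to (used for validation
#'   only; the ethogram itself lives on the containing [sequence_set()]).
#' @return An object of class `action_seq`.
#' @export
action_seq <- function(sequence_id, subject_id, group, actions,
                       ethogram = NULL) {
  actions <- as.integer(actions)
  if (length(actions) < 1) stop("a sequence must contain at least one action")
  if (anyNA(actions)) stop("actions must not contain NA")
  if (!is.null(ethogram) && any(!(actions %in% ethogram$codes))) {
    bad <- actions[!(actions %in% ethogram$codes)][1]
    stop("action code ", bad, " is not in the ethogram")
  }
  structure(list(sequence_id = as.character(sequence_id),
                 subject_id = as.character(subject_id),
                 group = as.character(group),
                 actions = actions),
            class = "action_seq")
}

#' Construct a set of action sequences sharing one ethogram
#'
#' @param ethogram an [ethogram()].
#' @param sequences list of [action_seq()] objects.
#' @param provenance free-text source tag.
#' @return An object of class `seq_set`.
#' @export
sequence_set <- function(ethogram, sequences = list(), provenance = "") {
  stopifnot(inherits(ethogram, "ethogram"))
  for (s in sequences) {
    stopifnot(inherits(s, "action_seq"))
    if (any(!(s$actions %in% ethogram$codes))) {
      stop("sequence ", s$sequence_id, " contains codes outside the ethogram")
    }
  }
  structure(list(ethogram = ethogram, sequences = sequences,
                 provenance = as.character(provenance)),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  n <- length(x$sequences)
  lens <- sequence_lengths(x)
  cat("<seq_set> ", n, " sequences over ", length(x$ethogram$labels),
      " behaviors", if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"),
      "\n", sep = "")
  if (n > 0) {
    cat("  lengths: min ", min(lens), ", median ", stats::median(lens),
        ", max ", max(lens), "\n", sep = "")
    cat("  groups: ", paste(unique(vapply(x$sequences, `[[`, "", "group")),
                            collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$sequences)

#' Sequence lengths of a set
#' @param set a [sequence_set()].
#' @return integer vector of per-sequence lengths (number of actions).
#' @export
sequence_lengths <- function(set) {
  vapply(set$sequences, function(s) length(s$actions), integer(1))
}

#' Convert a sequence set to a long data frame
#'
#' One row per action: `sequence_id, subject_id, group, position, behavior`
#' (the CSV dialect used by [read_sequences()] / [write_sequences()]).
#'
#' @param set a [sequence_set()].
#' @return data.frame in long format with 1-based contiguous positions.
#' @export
as_sequence_df <- function(set) {
  stopifnot(inherits(set, "seq_set"))
  if (length(set$sequences) == 0) {
    return(data.frame(sequence_id = character(), subject_id = character(),
                      group = character(), position = integer(),
                      behavior = character(), stringsAsFactors = FALSE))
  }
  parts <- lapply(set$sequences, function(s) {
    data.frame(sequence_id = s$sequence_id, subject_id = s$subject_id,
               group = s$group, position = seq_along(s$actions),
               behavior = set$ethogram$labels[s$actions],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Read ethogram-coded sequences from CSV
#'
#' Expects a UTF-8 CSV with header and columns
#' `sequence_id, subject_id, group, position, behavior` (the `column_map`
#' argument adapts other namings). `behavior` holds the label string;
#' positions are 1-based and must be contiguous within each sequence.
#'
#' @param path CSV file path.
#' @param ethogram optional [ethogram()] fixing the label-code mapping. If
#'   `NULL`, codes are assigned by first appearance in the file.
#' @param column_map named character vector mapping the canonical column
#'   names to the names actually present in the file, e.g.
#'   `c(sequence_id = "seq", behavior = "act")`. Unmapped columns keep the
#'   canonical name.
#' @param provenance free-text source tag stored on the returned set.
#' @return A [sequence_set()] with one sequence per distinct `sequence_id`,
#'   actions ordered by position. Sequence order follows first appearance.
#' @export
read_sequences <- function(path, ethogram = NULL, column_map = NULL,
                           provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  canonical <- c("sequence_id", "subject_id", "group", "position", "behavior")
  nmap <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad)) stop("unknown column_map entries: ", paste(bad, collapse = ", "))
    nmap[names(column_map)] <- column_map
  }
  missing_cols <- nmap[!(nmap %in% names(df))]
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, nmap]
  names(df) <- canonical
  df$position <- as.integer(df$position)
  sequence_set_from_df(df, ethogram = ethogram, provenance = provenance)
}

#' Build a sequence set from a long data frame
#'
#' @param df data.frame with columns `sequence_id, subject_id, group,
#'   position, behavior`.
#' @inheritParams read_sequences
#' @return A [sequence_set()].
#' @export
sequence_set_from_df <- function(df, ethogram = NULL, provenance = "") {
  if (nrow(df) == 0) {
    eth <- if (is.null(ethogram)) ethogram(c("(none)")) else ethogram
    return(sequence_set(eth, list(), provenance))
  }
  if (is.null(ethogram)) {
    eth <- ethogram(unique(df$behavior))
  } else {
    eth <- ethogram
    unknown <- setdiff(unique(df$behavior), eth$labels)
    if (length(unknown)) {
      row <- which(df$behavior == unknown[1])[1]
      stop("unknown behavior label '", unknown[1], "' at row ", row)
    }
  }
  code <- stats::setNames(eth$codes, eth$labels)
  ids <- unique(df$sequence_id)
  seqs <- lapply(ids, function(id) {
    sub <- df[df$sequence_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    if (!identical(as.integer(sub$position), seq_len(nrow(sub)))) {
      stop("positions for sequence '", id,
           "' are not contiguous 1..n (got: ",
           paste(utils::head(sub$position, 10), collapse = ","), " ...)")
    }
    if (length(unique(sub$subject_id)) > 1 || length(unique(sub$group)) > 1) {
      stop("sequence '", id, "' has inconsistent subject_id or group")
    }
    action_seq(id, sub$subject_id[1], sub$group[1],
               unname(code[sub$behavior]), ethogram = eth)
  })
  sequence_set(eth, seqs, provenance)
}

#' Write a sequence set to CSV
#'
#' Emits the same dialect [read_sequences()] reads, so
#' `read_sequences(write_sequences(set, f))` round-trips field for field.
#'
#' @param set a [sequence_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(set, path) {
  utils::write.csv(as_sequence_df(set), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read or write an ethogram file (`code,label` CSV)
#'
#' @param path CSV path with columns `code,label`; codes must be contiguous
#'   integers starting at 1.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "label") %in% names(df))) {
    stop("ethogram file needs columns code,label")
  }
  df <- df[order(as.integer(df$code)), ]
  if (!identical(as.integer(df$code), seq_len(nrow(df)))) {
    stop("ethogram codes must be contiguous integers starting at 1")
  }
  ethogram(df$label)
}

#' @rdname read_ethogram
#' @param eth an [ethogram()] to serialize.
#' @export
write_ethogram <- function(eth, path) {
  utils::write.csv(data.frame(code = eth$codes, label = eth$labels),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Drop sequences shorter than a minimum length
#'
#' Sequences shorter than 8 actions cannot contain a rule nested inside
#' another rule under Sequitur with K = 2, so the default mirrors the
#' analysis filter applied before computing hierarchical-complexity
#' metrics.
#'
#' @param set a [sequence_set()].
#' @param min_len minimum number of actions to keep (default 8).
#' @return list with `kept` (a [sequence_set()], original order preserved)
#'   and `n_removed`.
#' @export
filter_min_length <- function(set, min_len = 8L) {
  stopifnot(inherits(set, "seq_set"), min_len >= 1)
  keep <- sequence_lengths(set) >= min_len
  kept <- sequence_set(set$ethogram, set$sequences[keep], set$provenance)
  list(kept = kept, n_removed = sum(!keep))
}

#' Pooled behavior frequencies
#'
#' Relative frequency of each behavior code pooled over every action in
#' every sequence of the set (not averaged per sequence) — the empirical
#' distribution used to draw i.i.d. control sequences.
#'
#' @param set a non-empty [sequence_set()].
#' @return named numeric vector over all ethogram codes, summing to 1.
#' @export
behavior_frequencies <- function(set) {
  stopifnot(inherits(set, "seq_set"))
  all_actions <- unlist(lapply(set$sequences, `[[`, "actions"))
  if (length(all_actions) == 0) stop("sequence set contains no actions")
  counts <- tabulate(all_actions, nbins = length(set$ethogram$labels))
  stats::setNames(counts / sum(counts), set$ethogram$labels)
}
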