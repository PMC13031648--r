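#' Inventory of distinct rule structures in a group
#'
#' Deduplicates the binary tree-shape encodings of all rules found across a
#' group's sequences, keeping occurrence counts. Structure identity is the
#' shape encoding alone — terminal labels are ignored, which is what makes
#' structures comparable across behaviorally unrelated groups (observed vs
#' simulated).
#'
#' @param bits character vector of rule encodings (e.g., the `bits` column
#'   of a [set_metrics()] rules table).
#' @param group group label.
#' @return An object of class `structure_inventory`: list with `group` and
#'   `structures` (named integer vector: encoding -> count).
#' @export
build_inventory <- function(bits, group) {
  bits <- as.character(bits)
  for (b in bits) .check_bits(b)
  if (length(bits)) {
    n1 <- vapply(bits, function(b) unname(.count_bits(b)["n1"]), numeric(1))
    if (any(n1 < 2)) stop("invalid rule encoding (fewer than two 1s): ",
                          bits[n1 < 2][1])
  }
  tab <- table(bits)
  structure(list(group = as.character(group),
                 structures = stats::setNames(as.integer(tab), names(tab))),
            class = "structure_inventory")
}

#' @export
print.structure_inventory <- function(x, ...) {
  cat("<structure_inventory ", x$group, "> ", length(x$structures),
      " distinct structures, ", sum(x$structures), " rules\n", sep = "")
  invisible(x)
}

#' Classify a group's rule structures as shared or unique
#'
#' A structure of the target inventory is `shared` iff it appears in at
#' least one of the other inventories, `unique` otherwise. The order of
#' `others` never matters.
#'
#' @param target a [build_inventory()] result.
#' @param others list of other `structure_inventory` objects.
#' @return list with character vectors `shared` and `unique` (disjoint;
#'   their union is the target's distinct structures).
#' @export
classify_shared <- function(target, others) {
  stopifnot(inherits(target, "structure_inventory"))
  if (inherits(others, "structure_inventory")) others <- list(others)
  pool <- unique(unlist(lapply(others, function(o) names(o$structures))))
  keys <- names(target$structures)
  shared <- keys[keys %in% pool]
  list(shared = shared, unique = setdiff(keys, shared))
}

#' Label per-rule metrics rows as shared or unique
#'
#' @param rules per-rule metrics table with a `bits` column (from
#'   [set_metrics()]).
#' @param shared,unique character vectors from [classify_shared()]; every
#'   encoding in `rules$bits` must be in one of them.
#' @return the table with an added `status` column (`"shared"` /
#'   `"unique"`); row count preserved.
#' @export
label_rules <- function(rules, shared, unique) {
  status <- ifelse(rules$bits %in% shared, "shared",
                   ifelse(rules$bits %in% unique, "unique", NA_character_))
  if (anyNA(status)) {
    stop("encoding not in shared or unique set: ",
         rules$bits[is.na(status)][1])
  }
  rules$status <- status
  rules
}

#' Inventory / classification CSV writers
#' @param inv a `structure_inventory`.
#' @param path CSV path.
#' @export
write_inventory <- function(inv, path) {
  utils::write.csv(data.frame(group = inv$group,
                              bits = names(inv$structures),
                              count = unname(inv$structures)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inventory
#' @param classification result of [classify_shared()].
#' @param group group label for the CSV.
#' @export
write_classification <- function(classification, group, path) {
  df <- rbind(
    if (length(classification$shared))
      data.frame(group = group, bits = classification$shared, status = "shared"),
    if (length(classification$unique))
      data.frame(group = group, bits = classification$unique, status = "unique"))
  if (is.null(df)) df <- data.frame(group = character(), bits = character(),
                                    status = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
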