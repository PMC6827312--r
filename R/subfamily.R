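# Subfamily calling: size and taxonomic-diversity rules applied to a
# chosen partition, deterministic numbering, representative sampling.

#' Call subfamilies from a partition
#'
#' A connected cluster becomes a subfamily iff it has at least `min_size`
#' members and spans at least `min_distinct` distinct non-empty values at
#' the chosen taxonomic rank -- unless the cluster id is listed in
#' `overrides`, which waives the diversity requirement (for clusters whose
#' early, robust segregation justifies a subfamily despite a single taxon).
#' All other sequences are reported as nonclassified.
#'
#' @param partition an `ssn_partition`.
#' @param records a [seq_records] data frame covering every partition member.
#' @param min_size minimum cluster size (default 20).
#' @param diversity_rank taxonomic rank at which diversity is required
#'   (default `"class"`).
#' @param min_distinct minimum number of distinct non-empty values at that
#'   rank (default 2).
#' @param overrides integer cluster ids exempted from the diversity rule.
#' @return a `subfamily_call`: list with `subfamilies` (data frame `number`,
#'   `size`, `n_distinct`, `override`, `members` list-column), `membership`
#'   (named vector id -> subfamily number, NA when nonclassified),
#'   `nonclassified` (id vector), `threshold`, and `classified_fraction`.
#' @export
delineate <- function(partition, records, min_size = 20,
                      diversity_rank = "class", min_distinct = 2,
                      overrides = integer(0)) {
  stopifnot(diversity_rank %in% TAX_RANKS)
  ids <- names(partition)
  missing <- setdiff(ids, records$id)
  if (length(missing))
    stop("partition member(s) without a sequence record: ",
         paste(head(missing, 5), collapse = ", "))
  clusters <- cluster_members(partition)
  if (length(overrides)) {
    unknown <- setdiff(overrides, as.integer(names(clusters)))
    if (length(unknown))
      stop("override names nonexistent cluster(s): ",
           paste(unknown, collapse = ", "))
  }
  rank_val <- setNames(records[[diversity_rank]], records$id)
  called <- lapply(names(clusters), function(cl) {
    m <- clusters[[cl]]
    vals <- unique(rank_val[m])
    nd <- sum(nzchar(vals))
    ok <- length(m) >= min_size &&
      (nd >= min_distinct || as.integer(cl) %in% as.integer(overrides))
    list(cluster = as.integer(cl), ok = ok, members = m, n_distinct = nd,
         override = as.integer(cl) %in% as.integer(overrides) &&
           nd < min_distinct)
  })
  kept <- Filter(function(x) x$ok, called)
  sf <- label_subfamilies(lapply(kept, function(x)
    list(members = x$members, n_distinct = x$n_distinct,
         override = x$override)))
  membership <- setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_len(nrow(sf)))
    membership[sf$members[[i]]] <- sf$number[i]
  nonclassified <- ids[is.na(membership)]
  res <- structure(list(
    subfamilies = sf, membership = membership,
    nonclassified = nonclassified,
    threshold = attr(partition, "threshold"),
    classified_fraction = 1 - length(nonclassified) / length(ids)),
    class = "subfamily_call")
  ssn_msg(sprintf("delineation: %d subfamilies, %d/%d classified (%.1f%%)",
                  nrow(sf), length(ids) - length(nonclassified), length(ids),
                  100 * res$classified_fraction))
  res
}

#' Number subfamilies deterministically
#'
#' Subfamilies are numbered by descending size, ties broken by the
#' lexicographically smallest member id. Renumbering is idempotent. A
#' user-supplied ordering of member-id sets can replace the default rule.
#'
#' @param subfamilies list of lists, each with at least a `members`
#'   character vector (optionally `n_distinct`, `override`).
#' @param order_by optional explicit ordering (permutation of
#'   `seq_along(subfamilies)`).
#' @return data frame `number`, `size`, `n_distinct`, `override` with a
#'   `members` list-column, one row per subfamily, ordered by number.
#' @export
label_subfamilies <- function(subfamilies, order_by = NULL) {
  members <- lapply(subfamilies, `[[`, "members")
  sizes <- lengths(members)
  firsts <- vapply(members, function(m) min(m), character(1))
  o <- order_by %||% order(-sizes, firsts)
  df <- data.frame(
    number = seq_along(subfamilies),
    size = sizes[o],
    n_distinct = vapply(subfamilies[o], function(x)
      as.integer(x$n_distinct %||% NA_integer_), integer(1)),
    override = vapply(subfamilies[o], function(x)
      isTRUE(x$override), logical(1)))
  df$members <- members[o]
  df
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf(
    "<subfamily_call> %d subfamilies at threshold %s; %d nonclassified (%.1f%% classified)\n",
    nrow(x$subfamilies), format(x$threshold %||% NA),
    length(x$nonclassified), 100 * x$classified_fraction))
  print.data.frame(x$subfamilies[, c("number", "size", "n_distinct",
                                     "override")])
  invisible(x)
}

#' @export
summary.subfamily_call <- function(object, ...) {
  object$subfamilies[, c("number", "size", "n_distinct", "override")]
}

#' Sample representative sequences from a subfamily
#'
#' Returns all members when the subfamily has fewer than `n`, otherwise a
#' uniform random sample of `n` without replacement, reproducible under
#' `seed`. Intended for export as FASTA for external tree building.
#'
#' @param members character vector of member ids (or a one-row slice of the
#'   `subfamilies` table).
#' @param n sample size (default 30).
#' @param seed optional integer seed.
#' @return character vector of ids.
#' @export
sample_representatives <- function(members, n = 30, seed = NULL) {
  if (is.list(members)) members <- unlist(members, use.names = FALSE)
  stopifnot(n >= 1)
  if (length(members) <= n) return(members)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sample(members, n)
}

#' Write subfamily membership to a TSV file
#'
#' Columns: `id`, `subfamily` (empty for nonclassified sequences).
#'
#' @param call a `subfamily_call`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_membership <- function(call, path) {
  m <- call$membership
  df <- data.frame(id = names(m),
                   subfamily = ifelse(is.na(m), "", as.character(m)))
  df <- df[order(df$id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-subfamily summary to a TSV file
#'
#' Columns: `number`, `size`, `n_distinct`, `override`.
#'
#' @param call a `subfamily_call`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_subfamily_summary <- function(call, path) {
  write.table(summary(call), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
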