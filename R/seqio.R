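# Sequence and metadata input/output, and the fragment filter applied
# before any network analysis.

#' Construct a set of sequence records
#'
#' The central container is a data frame of class `seq_records` with one row
#' per protein: `id`, `seq`, `length`, the seven taxonomic ranks
#' (kingdom...species, empty string when unknown), and `is_fragment`.
#'
#' @param id character vector of unique accessions.
#' @param seq character vector of amino-acid sequences (uppercased; the 20
#'   canonical residues plus the ambiguity code X).
#' @param taxonomy optional data frame with the seven rank columns, recycled
#'   to empty strings when absent.
#' @param is_fragment logical flag per record (default `FALSE`).
#' @return a `seq_records` data frame.
#' @export
seq_records <- function(id, seq, taxonomy = NULL, is_fragment = FALSE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have the same length")
  if (any(!nzchar(id)))
    stop("empty sequence id")
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq)))
    stop("empty sequence for id(s): ", paste(id[!nzchar(seq)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(c(AA_ALPHABET20, "X"), collapse = ""), "]"),
               seq)
  if (any(bad))
    stop("non-amino-acid characters (beyond X) in record(s): ",
         paste(id[bad], collapse = ", "))
  df <- data.frame(id = id, seq = seq, length = nchar(seq),
                   stringsAsFactors = FALSE)
  if (is.null(taxonomy)) {
    for (r in TAX_RANKS) df[[r]] <- rep("", nrow(df))
  } else {
    stopifnot(all(TAX_RANKS %in% names(taxonomy)),
              nrow(taxonomy) == nrow(df))
    for (r in TAX_RANKS) df[[r]] <- as.character(taxonomy[[r]])
  }
  df$is_fragment <- rep_len(as.logical(is_fragment), nrow(df))
  class(df) <- c("seq_records", "data.frame")
  df
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d sequences, lengths %d-%d, %d fragment(s)\n",
              nrow(x), if (nrow(x)) min(x$length) else 0L,
              if (nrow(x)) max(x$length) else 0L, sum(x$is_fragment)))
  if (nrow(x)) {
    print.data.frame(head(as.data.frame(x)[, c("id", "length", "class")], 5))
    if (nrow(x) > 5) cat("  ... and", nrow(x) - 5, "more\n")
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased. Duplicate ids and residues outside the
#' 20-letter alphabet (plus X) are rejected.
#'
#' @param path path to a FASTA file.
#' @return a [seq_records] data frame (taxonomy empty, no fragments flagged).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seq_records(id = ids, seq = as.character(set))
}

#' Write sequence records to a FASTA file
#'
#' @param records a [seq_records] data frame (or anything with `id`/`seq`).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a taxonomy metadata table
#'
#' Expects a tab-separated file with header
#' `id kingdom phylum class order family genus species`.
#'
#' @param path path to the TSV file.
#' @return data frame with `id` plus the seven rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- 1L + length(TAX_RANKS)
  # header may legitimately have exactly `expected` columns too
  bad <- which(nf != expected)
  if (length(bad))
    stop(sprintf("malformed taxonomy row at line %d: %d column(s), expected %d",
                 bad[1], nf[bad[1]], expected))
  hdr <- fields[[1]]
  if (!identical(tolower(hdr), c("id", TAX_RANKS)))
    stop("taxonomy header must be: id ", paste(TAX_RANKS, collapse = " "))
  body <- fields[-1]
  out <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(out) <- c("id", TAX_RANKS)
  out
}

#' Attach taxonomy lineages to sequence records
#'
#' Records absent from the table keep seven empty ranks and trigger a
#' warning (not an error).
#'
#' @param records a [seq_records] data frame.
#' @param taxonomy data frame as returned by [read_taxonomy()], or a path to
#'   such a file.
#' @return the records with rank columns filled.
#' @export
attach_taxonomy <- function(records, taxonomy) {
  if (is.character(taxonomy) && length(taxonomy) == 1)
    taxonomy <- read_taxonomy(taxonomy)
  stopifnot(all(c("id", TAX_RANKS) %in% names(taxonomy)))
  idx <- match(records$id, taxonomy$id)
  missing <- records$id[is.na(idx)]
  if (length(missing))
    warning(length(missing), " record(s) missing from taxonomy table: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  for (r in TAX_RANKS) {
    v <- taxonomy[[r]][idx]
    v[is.na(v)] <- ""
    records[[r]] <- v
  }
  records
}

#' Read per-record family-model coverage
#'
#' Coverage is the fraction of family-model columns spanned by a record's
#' alignment to the model, in `[0, 1]`. It is accepted as precomputed input:
#' a two-column TSV (`id`, `model_coverage`), with or without a header line.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of coverages.
#' @export
read_coverage <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("coverage table must have 2 columns (id, coverage)")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  cov <- as.numeric(df[[2]])
  if (anyNA(cov)) stop("unparsable coverage value(s)")
  setNames(cov, as.character(df[[1]]))
}

#' Filter fragment sequences by family-model coverage
#'
#' Records covering less than `min_coverage` of the family model are flagged
#' as fragments and excluded from downstream analysis; coverage exactly at
#' the boundary is kept (the rule is strictly "less than").
#'
#' @param records a [seq_records] data frame.
#' @param coverage named numeric vector mapping id to coverage in `[0, 1]`.
#' @param min_coverage fragment boundary (default 0.95).
#' @return list with `kept` and `fragments`, both [seq_records]; their union
#'   is the input.
#' @export
filter_fragments <- function(records, coverage, min_coverage = 0.95) {
  cov <- coverage[records$id]
  if (anyNA(cov))
    stop("missing coverage for record(s): ",
         paste(head(records$id[is.na(cov)], 5), collapse = ", "))
  if (any(cov < 0 | cov > 1)) stop("coverage must be in [0, 1]")
  frag <- cov < min_coverage
  records$is_fragment <- unname(frag)
  kept <- records[!frag, , drop = FALSE]
  fragments <- records[frag, , drop = FALSE]
  rownames(kept) <- rownames(fragments) <- NULL
  class(kept) <- class(fragments) <- c("seq_records", "data.frame")
  ssn_msg(sprintf("fragment filter: %d kept, %d fragments (< %.0f%% coverage)",
                  nrow(kept), nrow(fragments), 100 * min_coverage))
  list(kept = kept, fragments = fragments)
}
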