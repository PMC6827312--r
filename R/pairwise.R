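# All-vs-all pairwise local-alignment statistics defining SSN edges:
# internal alignment via optimal affine-gap Smith-Waterman, or import of
# standard BLAST tabular ("outfmt 6") output.

# Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
# (the standard published values used by BLAST for this scoring system).
# Composition-based score adjustment is not applied, so E-values can differ
# slightly from blastp's.
KA_LAMBDA <- 0.267
KA_K <- 0.041

EVALUE_FLOOR <- 1e-180

#' Convert a raw local-alignment score to a bit score
#'
#' Uses gapped Karlin-Altschul parameters for BLOSUM62/11/1:
#' `bits = (lambda * S - ln K) / ln 2`.
#'
#' @param raw_score raw Smith-Waterman score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return bit score(s).
#' @export
raw_to_bit <- function(raw_score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Compute an E-value from a bit score
#'
#' `E = m * n * 2^(-bits)`, where `m` is the query length and `n` the total
#' residue count of the search database. Strictly decreasing in the bit
#' score for fixed search space; floored at `1e-180` so log-binning over the
#' threshold grid is always defined.
#'
#' @param bit_score bit score(s).
#' @param m query length (> 0).
#' @param n database residue total (> 0).
#' @param floor lower bound applied to the result.
#' @return E-value(s).
#' @export
compute_evalue <- function(bit_score, m, n, floor = EVALUE_FLOOR) {
  if (any(m <= 0) || any(n <= 0)) stop("search-space sizes m, n must be > 0")
  pmax(as.numeric(m) * as.numeric(n) * 2^(-bit_score), floor)
}

#' Optimal affine-gap local alignment of two sequences
#'
#' Smith-Waterman alignment under BLOSUM62 with BLAST-style affine gap costs
#' (a gap of length L costs `gap_open + L * gap_extend`). Identity and
#' alignment length are computed over the optimal local alignment path. A
#' pair with no positive-scoring local alignment gets score 0.
#'
#' @param a,b amino-acid strings (or single-row [seq_records]).
#' @param gap_open,gap_extend gap penalties (default 11 and 1).
#' @return list with `score`, `identity_pct`, `align_length`.
#' @export
local_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (is.data.frame(a)) a <- a$seq[1]
  if (is.data.frame(b)) b <- b$seq[1]
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, identity_pct = 0, align_length = 0L))
  len <- Biostrings::nchar(aln)
  list(score = sc,
       identity_pct = 100 * Biostrings::nmatch(aln) / len,
       align_length = len)
}

#' @noRd
new_hit_table <- function(df, n_db_residues) {
  df <- df[order(df$query_id, df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_db_residues") <- n_db_residues
  class(df) <- c("hit_table", "data.frame")
  df
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d unordered pairs (db = %s residues)\n",
              nrow(x), format(attr(x, "n_db_residues"))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' All-versus-all pairwise local alignments
#'
#' Evaluates every unordered sequence pair once (self-hits excluded) and
#' retains pairs whose E-value is at or below a reporting ceiling, by
#' default `1e-5`, the loosest threshold analysed downstream. E-values use
#' the query length times the total residue count of the set as search
#' space; the pair's E is the minimum over the two query directions. Pairs
#' are stored with lexicographically ordered ids, so the result is invariant
#' to input order.
#'
#' @param records a [seq_records] data frame with at least two rows.
#' @param ceiling reporting ceiling on the E-value (default `1e-5`).
#' @param gap_open,gap_extend gap penalties (default 11 and 1).
#' @return a `hit_table`: data frame with columns `query_id`, `subject_id`,
#'   `evalue`, `bit_score`, `identity_pct`, `align_length`.
#' @export
all_vs_all <- function(records, ceiling = 1e-5, gap_open = 11,
                       gap_extend = 1) {
  if (nrow(records) < 2) stop("all_vs_all needs at least 2 records")
  ord <- order(records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  n_db <- sum(nchar(seqs))
  set <- Biostrings::AAStringSet(setNames(seqs, ids))
  rows <- vector("list", length(ids) - 1L)
  for (i in seq_len(length(ids) - 1L)) {
    js <- (i + 1L):length(ids)
    aln <- Biostrings::pairwiseAlignment(
      set[js], set[[i]],
      substitutionMatrix = blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend, type = "local")
    sc <- Biostrings::score(aln)
    pos <- sc > 0
    if (!any(pos)) next
    bits <- raw_to_bit(sc[pos])
    # min over both query directions = use the shorter sequence as query
    m <- pmin(nchar(seqs[i]), nchar(seqs)[js][pos])
    ev <- compute_evalue(bits, m, n_db)
    keep <- ev <= ceiling
    if (!any(keep)) next
    len <- Biostrings::nchar(aln)[pos][keep]
    rows[[i]] <- data.frame(
      query_id = ids[i], subject_id = ids[js][pos][keep],
      evalue = ev[keep], bit_score = bits[keep],
      identity_pct = 100 * Biostrings::nmatch(aln)[pos][keep] / len,
      align_length = len, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(df))
    df <- data.frame(query_id = character(), subject_id = character(),
                     evalue = numeric(), bit_score = numeric(),
                     identity_pct = numeric(), align_length = integer(),
                     stringsAsFactors = FALSE)
  new_hit_table(df, n_db)
}

#' @noRd
collapse_pairs <- function(df) {
  # one entry per unordered pair: minimum E, ties broken by max bit score
  a <- pmin(df$query_id, df$subject_id)
  b <- pmax(df$query_id, df$subject_id)
  df$query_id <- a; df$subject_id <- b
  o <- order(a, b, df$evalue, -df$bit_score)
  df <- df[o, , drop = FALSE]
  df[!duplicated(paste0(df$query_id, "\r", df$subject_id)), , drop = FALSE]
}

#' Parse BLAST tabular output into a hit table
#'
#' Reads 12-column "outfmt 6" rows (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`), drops self-rows,
#' collapses directional rows and multiple HSPs per pair to a single entry
#' keeping the minimum E-value (ties: maximum bit score), and floors
#' E-values printed as 0 at `1e-180`.
#'
#' @param path path to the tabular file.
#' @return a `hit_table`.
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 bad[1], nf[bad[1]]))
  m <- do.call(rbind, fields)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  bs <- suppressWarnings(as.numeric(m[, 12]))
  pid <- suppressWarnings(as.numeric(m[, 3]))
  alen <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(ev) || anyNA(bs))
    stop("unparsable E-value or bit score at line ",
         which(is.na(ev) | is.na(bs))[1])
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   evalue = pmax(ev, EVALUE_FLOOR), bit_score = bs,
                   identity_pct = pid, align_length = alen,
                   stringsAsFactors = FALSE)
  df <- df[df$query_id != df$subject_id, , drop = FALSE]
  new_hit_table(collapse_pairs(df), NA_real_)
}

#' Write a hit table in the BLAST 12-column tabular dialect
#'
#' Emits one row per unordered pair. Columns the internal aligner does not
#' track (mismatch, gap opens, coordinates) are filled with best-effort
#' values (mismatches from identity and length; coordinates as 1..length).
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  nident <- round(hits$identity_pct / 100 * hits$align_length)
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$identity_pct), hits$align_length,
                    hits$align_length - nident, 0L, 1L, hits$align_length,
                    1L, hits$align_length,
                    format(hits$evalue, digits = 3, scientific = TRUE),
                    sprintf("%.1f", hits$bit_score))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
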