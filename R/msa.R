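# Redundancy reduction and a built-in progressive multiple aligner
# (guide tree from pairwise identities, profile-profile merges), with a
# pluggable hook for an external aligner.

#' Greedy redundancy reduction by pairwise identity
#'
#' Sequences are visited in order of decreasing length; each joins the
#' first existing representative it matches at `>= identity` (identity
#' computed over the optimal local alignment), otherwise it becomes a new
#' representative. Every input is therefore within `identity` of some
#' representative or is itself one.
#'
#' @param records a [seq_records] data frame.
#' @param identity fractional identity threshold in `(0, 1]` (default 0.75).
#' @return list with `representatives` ([seq_records]) and `assignment`
#'   (named vector input id -> representative id).
#' @export
reduce_redundancy <- function(records, identity = 0.75) {
  if (nrow(records) == 0) stop("empty input")
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  ord <- order(-records$length, records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  rep_idx <- integer(0)
  assignment <- setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    assigned <- FALSE
    if (length(rep_idx)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs[rep_idx]), Biostrings::AAString(seqs[i]),
        substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
        type = "local")
      frac <- ifelse(Biostrings::score(aln) > 0,
                     Biostrings::nmatch(aln) / Biostrings::nchar(aln), 0)
      hit <- which(frac >= identity)
      if (length(hit)) {
        assignment[i] <- ids[rep_idx[hit[1]]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- ids[i]
    }
  }
  keep <- records[match(ids[rep_idx], records$id), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("seq_records", "data.frame")
  list(representatives = keep, assignment = assignment)
}

# Residue-frequency profile (20 x L) of an alignment block; gaps and
# ambiguity codes carry no mass.
#' @noRd
block_profile <- function(block) {
  mat <- do.call(rbind, strsplit(block, ""))
  L <- ncol(mat)
  prof <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_ALPHABET20, NULL))
  for (a in AA_ALPHABET20) prof[a, ] <- colSums(mat == a)
  prof / nrow(mat)
}

#' @noRd
merge_blocks <- function(b1, b2, sub, gap_open, gap_ext) {
  path <- profile_align_path(block_profile(b1), block_profile(b2),
                             sub, gap_open, gap_ext)
  i <- cumsum(path != 2L)  # consumed columns of block 1
  j <- cumsum(path != 1L)  # consumed columns of block 2
  expand <- function(block, take, idx) {
    mat <- do.call(rbind, strsplit(block, ""))
    out <- matrix("-", nrow = nrow(mat), ncol = length(path))
    out[, take] <- mat[, idx[take], drop = FALSE]
    setNames(apply(out, 1, paste, collapse = ""), names(block))
  }
  c(expand(b1, path != 2L, i), expand(b2, path != 1L, j))
}

#' Multiple sequence alignment of a set of sequences
#'
#' Default engine: progressive alignment along a guide tree built by
#' average-linkage clustering of pairwise local-alignment identities, with
#' profile-profile merges scored by expected BLOSUM62 substitution score
#' under affine gap costs. A function can be supplied via `engine` to plug
#' in an external aligner; it must accept a [seq_records] data frame and
#' return a named character vector of equal-length gapped rows.
#'
#' @param records a [seq_records] data frame (at least one row).
#' @param gap_open,gap_extend profile-level gap penalties.
#' @param engine optional replacement aligner function.
#' @return named character vector of gapped rows (names = ids, all rows the
#'   same width); de-gapping any row reproduces its input sequence.
#' @export
build_msa <- function(records, gap_open = 11, gap_extend = 1, engine = NULL) {
  if (nrow(records) == 0) stop("empty input")
  if (!is.null(engine)) return(engine(records))
  rows <- setNames(records$seq, records$id)
  n <- length(rows)
  if (n == 1) return(rows)
  if (n == 2) {
    return(merge_blocks(rows[1], rows[2],
                        blosum62()[1:20, 1:20], gap_open, gap_extend))
  }
  # guide tree from pairwise identity fractions
  idm <- matrix(1, n, n)
  set <- Biostrings::AAStringSet(rows)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      set[js], set[[i]], substitutionMatrix = blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend, type = "local")
    frac <- ifelse(Biostrings::score(aln) > 0,
                   Biostrings::nmatch(aln) / Biostrings::nchar(aln), 0)
    idm[i, js] <- idm[js, i] <- frac
  }
  tree <- hclust(as.dist(1 - idm), method = "average")
  sub <- blosum62()[1:20, 1:20]
  blocks <- vector("list", nrow(tree$merge))
  node_block <- function(k) {
    if (k < 0) rows[-k] else blocks[[k]]
  }
  for (m in seq_len(nrow(tree$merge))) {
    blocks[[m]] <- merge_blocks(node_block(tree$merge[m, 1]),
                                node_block(tree$merge[m, 2]),
                                sub, gap_open, gap_extend)
  }
  out <- blocks[[nrow(tree$merge)]]
  out[records$id]
}
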