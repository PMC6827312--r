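# Synthetic protein families with known subfamily structure, taxonomy and
# fragments, so every pipeline stage is testable without external data.

# Substitution proposal: P(b | a) proportional to q_b * 2^(S_ab / 2) for
# b != a, the BLOSUM62 conditional target distribution (half-bit scores),
# so synthetic divergence behaves like real protein drift under the
# scoring matrix used downstream.
#' @noRd
blosum_conditional <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      S <- blosum62()[AA_ALPHABET20, AA_ALPHABET20]
      P <- sweep(2^(S / 2), 2, AA_BACKGROUND, `*`)
      diag(P) <- 0
      cache <<- P / rowSums(P)
    }
    cache
  }
})

#' Validate a synthetic-family configuration
#'
#' @param k number of subfamilies.
#' @param sizes per-subfamily member counts (recycled to length `k`).
#' @param seq_length ancestor length in residues (default 250, matching
#'   typical single-domain glycoside hydrolase modules).
#' @param within_divergence,between_divergence expected substitutions per
#'   site within a subfamily and from the family root to each subfamily
#'   ancestor; within must be smaller than between.
#' @param indel_rate expected indel events per site per sequence.
#' @param fragment_fraction fraction of records truncated below the 95%
#'   coverage boundary.
#' @param classes_per_subfamily taxonomy plan: number of distinct classes
#'   per subfamily (recycled; 1 = "monotaxon" subfamily exercising the
#'   diversity-override path).
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(k = 5, sizes = 40, seq_length = 250,
                         within_divergence = 0.15,
                         between_divergence = 0.5,
                         indel_rate = 0.004, fragment_fraction = 0,
                         classes_per_subfamily = 2, seed = 1) {
  stopifnot(k >= 1, all(sizes >= 1), seq_length >= 30,
            within_divergence >= 0, between_divergence > within_divergence,
            indel_rate >= 0, indel_rate < 1,
            fragment_fraction >= 0, fragment_fraction < 1)
  structure(list(k = as.integer(k),
                 sizes = rep_len(as.integer(sizes), k),
                 seq_length = as.integer(seq_length),
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 indel_rate = indel_rate,
                 fragment_fraction = fragment_fraction,
                 classes_per_subfamily = rep_len(as.integer(classes_per_subfamily), k),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Mutate a protein sequence
#'
#' Applies `n_substitutions` substitutions at distinct positions, each new
#' residue drawn from the BLOSUM62-conditional distribution given the old
#' one (never the identity), then `indel_events` insertions/deletions of
#' geometric length (mean 2) at random positions. Deterministic under
#' `seed`; with `seed = NULL` the current RNG stream is used.
#'
#' @param seq amino-acid string.
#' @param n_substitutions number of substituted positions (at most the
#'   sequence length).
#' @param indel_events number of indel events (default 0).
#' @param seed optional integer seed.
#' @return the mutated sequence string.
#' @export
mutate_sequence <- function(seq, n_substitutions, indel_events = 0,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chars <- strsplit(seq, "")[[1]]
  if (n_substitutions > length(chars))
    stop("more substitution positions requested than sequence length")
  if (n_substitutions > 0) {
    P <- blosum_conditional()
    pos <- sample.int(length(chars), n_substitutions)
    for (p in pos) {
      a <- chars[p]
      if (a %in% AA_ALPHABET20)
        chars[p] <- sample(AA_ALPHABET20, 1, prob = P[a, ])
    }
  }
  for (e in seq_len(indel_events)) {
    len <- rgeom_len()
    if (runif(1) < 0.5 && length(chars) > len + 10) {  # deletion
      start <- sample.int(length(chars) - len, 1)
      chars <- chars[-(start:(start + len - 1L))]
    } else {                                           # insertion
      ins <- sample(AA_ALPHABET20, len, replace = TRUE,
                    prob = AA_BACKGROUND)
      at <- sample.int(length(chars) + 1L, 1) - 1L
      chars <- append(chars, ins, after = at)
    }
  }
  paste(chars, collapse = "")
}

#' @noRd
rgeom_len <- function() 1L + stats::rgeom(1, 0.5)

#' @noRd
random_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}

#' Generate a synthetic protein family with known subfamily structure
#'
#' One ancestor per subfamily is derived from a common family root by
#' `between_divergence` substitutions per site; members mutate their
#' ancestor at `within_divergence` with Poisson-distributed indel events.
#' Taxonomy labels follow the class plan; a `fragment_fraction` of records
#' is truncated to a uniform 30-90% window of the model length and flagged
#' in the truth table. Fully reproducible under the config seed.
#'
#' @param config a [synth_config()].
#' @return list with `records` ([seq_records], taxonomy attached and
#'   fragments truncated) and `truth` (data frame `id`, `subfamily`,
#'   `is_fragment`, `model_coverage`).
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  L <- config$seq_length
  root <- random_protein(L)
  n_between <- min(L, round(config$between_divergence * L))
  n_within <- min(L, round(config$within_divergence * L))
  ids <- character(0); seqs <- character(0)
  subfam <- integer(0); cls <- character(0); phyl <- character(0)
  king <- character(0)
  for (f in seq_len(config$k)) {
    ancestor <- mutate_sequence(root, n_between, indel_events = 1)
    classes <- sprintf("Class_%d_%d", f,
                       seq_len(config$classes_per_subfamily[f]))
    for (i in seq_len(config$sizes[f])) {
      id <- sprintf("SF%02d_%04d", f, i)
      n_indel <- rpois(1, config$indel_rate * L)
      seqs <- c(seqs, mutate_sequence(ancestor, n_within, n_indel))
      ids <- c(ids, id)
      subfam <- c(subfam, f)
      cls <- c(cls, classes[1L + (i - 1L) %% length(classes)])
      phyl <- c(phyl, sprintf("Phylum_%d", f))
      king <- c(king, if (f %% 2) "Bacteria" else "Eukaryota")
    }
  }
  coverage <- rep(1, length(ids))
  is_frag <- rep(FALSE, length(ids))
  n_frag <- ceiling(config$fragment_fraction * length(ids))
  if (n_frag > 0) {
    frag_idx <- sample(seq_along(ids), n_frag)
    for (j in frag_idx) {
      u <- runif(1, 0.30, 0.90)
      keep <- max(15L, round(u * L))
      start <- sample.int(max(1L, nchar(seqs[j]) - keep + 1L), 1)
      seqs[j] <- substr(seqs[j], start, start + keep - 1L)
      coverage[j] <- keep / L
      is_frag[j] <- TRUE
    }
  }
  taxonomy <- data.frame(
    kingdom = king, phylum = phyl, class = cls,
    order = paste0("Order_", subfam), family = "SynthFam",
    genus = sub("_.*", "", cls), species = paste0("sp_", ids),
    stringsAsFactors = FALSE)
  records <- seq_records(ids, seqs, taxonomy = taxonomy,
                         is_fragment = is_frag)
  truth <- data.frame(id = ids, subfamily = subfam, is_fragment = is_frag,
                      model_coverage = coverage, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Named benchmark presets
#'
#' \describe{
#'   \item{`five_families_small`}{200 sequences in 5 subfamilies of 40,
#'     each spanning 2 taxonomic classes; designed so a contiguous window
#'     of the default threshold grid recovers the truth partition.}
#'   \item{`singletons_divergent`}{50 mutually divergent sequences
#'     (independent random proteins, pairwise identity below 30%); truth is
#'     50 singletons.}
#'   \item{`two_families_with_fragments`}{73 sequences in 2 subfamilies
#'     (40 + 33, one of them monotaxon), with exactly 10 truncated
#'     fragment records.}
#' }
#'
#' @param profile preset name.
#' @param seed RNG seed (default 1).
#' @return list with `records` and `truth` as in [generate_families()].
#' @export
synth_preset <- function(profile = c("five_families_small",
                                     "singletons_divergent",
                                     "two_families_with_fragments"),
                         seed = 1) {
  profile <- match.arg(profile)
  switch(profile,
    five_families_small = generate_families(
      synth_config(k = 5, sizes = 40, seq_length = 250,
                   within_divergence = 0.15, between_divergence = 0.5,
                   indel_rate = 0.004, classes_per_subfamily = 2,
                   seed = seed)),
    singletons_divergent = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      ids <- sprintf("DIV_%03d", seq_len(50))
      seqs <- vapply(ids, function(i) random_protein(250), character(1))
      taxonomy <- data.frame(
        kingdom = "Bacteria", phylum = paste0("Phylum_", seq_len(50)),
        class = paste0("Class_", seq_len(50)),
        order = paste0("Order_", seq_len(50)), family = "SynthDiv",
        genus = paste0("Genus_", seq_len(50)), species = paste0("sp_", ids),
        stringsAsFactors = FALSE)
      list(records = seq_records(ids, seqs, taxonomy = taxonomy),
           truth = data.frame(id = ids, subfamily = seq_len(50),
                              is_fragment = FALSE, model_coverage = 1,
                              stringsAsFactors = FALSE))
    },
    two_families_with_fragments = generate_families(
      synth_config(k = 2, sizes = c(40, 33), seq_length = 250,
                   within_divergence = 0.15, between_divergence = 0.5,
                   indel_rate = 0.004, fragment_fraction = 10 / 73,
                   classes_per_subfamily = c(2, 1), seed = seed)))
}

#' Write a benchmark fixture bundle to disk
#'
#' Writes `sequences.fasta`, `taxonomy.tsv`, `coverage.tsv` and `truth.tsv`
#' into a directory, consumable directly by the pipeline; the truth file
#' enables end-to-end scoring.
#'
#' @param profile preset name (see [synth_preset()]).
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return the directory path, invisibly.
#' @export
make_benchmark_fixture <- function(profile, dir, seed = 1) {
  bundle <- synth_preset(profile, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$records, file.path(dir, "sequences.fasta"))
  tax <- data.frame(id = bundle$records$id,
                    bundle$records[, TAX_RANKS, drop = FALSE])
  write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$truth[, c("id", "model_coverage")],
              file.path(dir, "coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
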