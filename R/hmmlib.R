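# The S+1 per-subfamily HMM library: build, scan, assign, serialize.

#' Build the S+1 profile-HMM library for a subfamily partition
#'
#' For each subfamily: reduce redundancy at the given identity, align the
#' representatives, and build a calibrated profile HMM. One additional
#' "remainder" model is built from the nonclassified sequences. When every
#' sequence is classified the remainder set is empty, and the remainder
#' model degenerates to a background model (trained on seeded random
#' sequences of background composition) that exists so the library always
#' holds S+1 models but attracts no assignments.
#'
#' @param records a [seq_records] data frame.
#' @param membership named vector id -> subfamily number (`NA` for
#'   nonclassified), e.g. the `membership` field of a `subfamily_call`, or
#'   a reference partition of your own.
#' @param identity redundancy-reduction identity (default 0.75).
#' @param pseudocount emission/transition pseudocount weight.
#' @param n_calib,calib_seed calibration draws and seed per model.
#' @param msa_engine optional external-aligner hook passed to [build_msa()].
#' @return an `hmm_library`: list with `models` (named list of
#'   `profile_hmm`; the remainder model is named `"remainder"`) and
#'   `search_space` (number of models, used for E-values).
#' @export
build_hmm_library <- function(records, membership, identity = 0.75,
                              pseudocount = 1, n_calib = 200, calib_seed = 7,
                              msa_engine = NULL) {
  membership <- membership[records$id]
  groups <- split(records$id, membership[records$id])
  if (length(groups) == 0) stop("no subfamily has any member")
  nonclassified <- records$id[is.na(membership)]
  models <- vector("list", length(groups) + 1L)
  names(models) <- c(names(groups), "remainder")
  for (g in names(groups)) {
    models[[g]] <- train_subfamily_hmm(
      records[records$id %in% groups[[g]], , drop = FALSE],
      name = g, identity = identity, pseudocount = pseudocount,
      n_calib = n_calib, calib_seed = calib_seed, msa_engine = msa_engine)
  }
  rem <- if (length(nonclassified)) {
    records[records$id %in% nonclassified, , drop = FALSE]
  } else {
    # degenerate background remainder: random sequences of background
    # composition, so the "+1" slot exists without competing with the
    # subfamily models
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(calib_seed + 1L)
    L <- round(stats::median(records$length))
    bg <- seq_records(sprintf("background_%02d", 1:20),
                      vapply(1:20, function(i) random_protein(L),
                             character(1)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    bg
  }
  models[["remainder"]] <- train_subfamily_hmm(
    rem, name = "remainder", identity = identity, pseudocount = pseudocount,
    n_calib = n_calib, calib_seed = calib_seed, msa_engine = msa_engine,
    relax_gap_rule = TRUE)
  structure(list(models = models, search_space = length(models)),
            class = "hmm_library")
}

#' @noRd
train_subfamily_hmm <- function(recs, name, identity, pseudocount, n_calib,
                                calib_seed, msa_engine,
                                relax_gap_rule = FALSE) {
  recs <- recs[order(recs$id), , drop = FALSE]
  class(recs) <- c("seq_records", "data.frame")
  red <- reduce_redundancy(recs, identity = identity)
  msa <- build_msa(red$representatives, engine = msa_engine)
  build <- function(max_gap) {
    build_profile_hmm(msa, name = name, pseudocount = pseudocount,
                      max_gap_frac = max_gap, calibrate = TRUE,
                      n_calib = n_calib, calib_seed = calib_seed)
  }
  if (!relax_gap_rule) return(build(0.5))
  # highly divergent remainder alignments can leave no column with a gap
  # majority; widen the rule just enough to keep a model
  tryCatch(build(0.5), error = function(e) {
    mat <- do.call(rbind, strsplit(msa, ""))
    gf <- colMeans(mat == "-")
    build(min(1, quantile(gf, 0.25) + 1e-9))
  })
}

#' @export
print.hmm_library <- function(x, ...) {
  cat(sprintf("<hmm_library> %d models (S = %d subfamilies + remainder)\n",
              length(x$models), length(x$models) - 1L))
  invisible(x)
}

#' Scan sequences against an HMM library and apply the assignment rule
#'
#' Every sequence is scored against all models; models are ranked by
#' E-value (ties by bit score). The subfamily of the best model is
#' predicted only if (i) the best E-value is below `best_ceiling` and
#' (ii) the second-best model's E-value is at least `fold` times greater
#' (i.e. less significant); when only one model hits, the second-best E is
#' taken as infinite. A best hit on the remainder model never yields a
#' subfamily prediction.
#'
#' @param records a [seq_records] data frame (or a single sequence string).
#' @param library an `hmm_library`.
#' @param best_ceiling condition (i) ceiling (default `1e-30`).
#' @param fold condition (ii) fold factor (default `1e10`).
#' @return an `hmm_assignment` data frame: `id`, `best_model`, `e_best`,
#'   `e_second`, `bit_best`, `predicted` (subfamily label or `NA`).
#' @export
assign_subfamily <- function(records, library, best_ceiling = 1e-30,
                             fold = 1e10) {
  if (is.character(records))
    records <- seq_records(id = paste0("query", seq_along(records)),
                           seq = records)
  stopifnot(inherits(library, "hmm_library"), length(library$models) >= 1)
  Z <- library$search_space
  out <- lapply(seq_len(nrow(records)), function(i) {
    sc <- lapply(library$models, function(m)
      score_sequence(records$seq[i], m, search_space = Z))
    ev <- vapply(sc, `[[`, numeric(1), "evalue")
    bits <- vapply(sc, `[[`, numeric(1), "bit_score")
    o <- order(ev, -bits)
    e_best <- ev[o[1]]
    e_second <- if (length(ev) >= 2) ev[o[2]] else Inf
    best_model <- names(library$models)[o[1]]
    data.frame(id = records$id[i], best_model = best_model,
               e_best = e_best, e_second = e_second,
               bit_best = bits[o[1]], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$predicted <- apply_assignment_rule(df, best_ceiling, fold)
  class(df) <- c("hmm_assignment", "data.frame")
  df
}

# The two-condition rule, reusable at different ceilings over the same scan.
#' @noRd
apply_assignment_rule <- function(df, best_ceiling, fold) {
  ok <- df$best_model != "remainder" &
    df$e_best < best_ceiling &
    (is.infinite(df$e_second) | df$e_second / df$e_best >= fold)
  ifelse(ok, df$best_model, NA_character_)
}

#' @export
print.hmm_assignment <- function(x, ...) {
  cat(sprintf("<hmm_assignment> %d sequences, %d with a prediction\n",
              nrow(x), sum(!is.na(x$predicted))))
  print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Write assignments to a TSV file
#'
#' Columns: `id`, `predicted`, `e_best`, `e_second`.
#'
#' @param assignments an `hmm_assignment` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_assignments <- function(assignments, path) {
  df <- assignments[, c("id", "predicted", "e_best", "e_second")]
  df$predicted[is.na(df$predicted)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an HMM library to a JSON-lines file
#'
#' One model per line: name, match emissions, insert emissions,
#' transitions, background, training length and calibration.
#'
#' @param library an `hmm_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library$models) {
    rec <- list(name = m$name, M = m$M,
                match_emissions = unname(m$match_emissions),
                insert_emissions = unname(m$insert_emissions),
                transitions = unname(m$transitions),
                background = unname(m$background),
                train_length = m$train_length,
                calibration = m$calibration)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read an HMM library from a JSON-lines file
#'
#' @param path path written by [write_hmm_library()].
#' @return an `hmm_library`.
#' @export
read_hmm_library <- function(path) {
  lines <- readLines(path)
  models <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    # jsonlite round-trips matrices with their dimensions intact
    me <- rec$match_emissions
    dimnames(me) <- list(NULL, AA_ALPHABET20)
    tr <- rec$transitions
    dimnames(tr) <- list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD"))
    structure(list(name = rec$name, M = rec$M, match_emissions = me,
                   insert_emissions = setNames(rec$insert_emissions,
                                               AA_ALPHABET20),
                   transitions = tr,
                   background = setNames(rec$background, AA_ALPHABET20),
                   train_length = rec$train_length,
                   calibration = rec$calibration),
              class = "profile_hmm")
  })
  names(models) <- vapply(models, `[[`, character(1), "name")
  structure(list(models = models, search_space = length(models)),
            class = "hmm_library")
}
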