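# Precision/recall evaluation of an HMM library against a reference
# subfamily partition, over a grid of E-value cutoffs.

#' Evaluate HMM-library predictions against a reference partition
#'
#' For each E-value cutoff the two-condition assignment rule is re-applied
#' with that cutoff as the best-hit ceiling (the fold condition is kept
#' fixed), and predictions are compared with the reference:
#' \itemize{
#'   \item TP: the predicted subfamily equals the reference subfamily;
#'   \item FP: a prediction was made but the reference differs or the
#'     protein has no reference subfamily;
#'   \item FN: the protein has a reference subfamily but received no
#'     prediction (a wrong prediction is an FP only, not also an FN).
#' }
#' Precision is `TP / (TP + FP)` and recall `TP / (TP + FN)`. With zero
#' predictions, precision is reported as 1 by convention (vacuous truth)
#' so curves are total functions; such rows are flagged.
#'
#' @param assignments an `hmm_assignment` data frame (from
#'   [assign_subfamily()]); its stored `e_best`/`e_second`/`best_model`
#'   fields are reused at every cutoff.
#' @param reference named vector id -> subfamily label (`NA` or missing
#'   entry = not assigned by the reference).
#' @param cutoffs E-value ceilings (default `10^-seq(5, 60, 5)`).
#' @param fold fold factor of condition (ii) (default `1e10`).
#' @return a `pr_table` data frame: `cutoff`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `vacuous_precision`.
#' @export
evaluate_library <- function(assignments, reference,
                             cutoffs = 10^-seq(5, 60, by = 5),
                             fold = 1e10) {
  unknown <- setdiff(assignments$id, names(reference))
  if (length(unknown))
    stop("prediction(s) for id(s) absent from the reference: ",
         paste(head(unknown, 5), collapse = ", "))
  ref <- as.character(reference[assignments$id])
  has_ref <- !is.na(ref) & nzchar(ref)
  rows <- lapply(cutoffs, function(cut) {
    pred <- apply_assignment_rule(assignments, best_ceiling = cut,
                                  fold = fold)
    has_pred <- !is.na(pred)
    tp <- sum(has_pred & has_ref & pred == ref, na.rm = TRUE)
    fp <- sum(has_pred) - tp
    fn <- sum(has_ref & !has_pred)
    vac <- tp + fp == 0
    data.frame(cutoff = cut, tp = tp, fp = fp, fn = fn,
               precision = if (vac) 1 else tp / (tp + fp),
               recall = if (tp + fn == 0) 1 else tp / (tp + fn),
               vacuous_precision = vac)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("pr_table", "data.frame")
  df
}

#' @export
print.pr_table <- function(x, ...) {
  cat("<pr_table> precision/recall over", nrow(x), "HMM E-value cutoffs\n")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Plot a precision-recall table
#'
#' @param x a `pr_table`.
#' @param ... passed to [plot()].
#' @export
plot.pr_table <- function(x, ...) {
  plot(x$recall, x$precision, type = "b", pch = 16, xlim = c(0, 1),
       ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = "HMM library performance", ...)
  invisible(x)
}

#' Write a precision-recall table to a TSV file
#'
#' @param pr a `pr_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pr_table <- function(pr, path) {
  write.table(as.data.frame(pr), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
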