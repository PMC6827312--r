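# Threshold-grid scan: one partition per E-value cutoff, with
# parent -> child refinement links between adjacent thresholds.

#' Default E-value threshold grid
#'
#' `1e-5` down to `1e-120` in steps of 5 log units (24 thresholds).
#'
#' @return numeric vector, strictly decreasing.
#' @export
default_threshold_grid <- function() 10^(-seq(5, 120, by = 5))

#' Scan an SSN over a grid of E-value thresholds
#'
#' Computes the connected-component partition at every threshold of a
#' strictly decreasing grid, and links each cluster at a stricter threshold
#' to the unique cluster containing it at the adjacent looser threshold.
#' Because the edge set at a stricter threshold is a subset of the looser
#' one, partitions refine monotonically and the component count never
#' decreases as the threshold tightens.
#'
#' @param hits a `hit_table`.
#' @param node_ids character vector of all sequence ids.
#' @param thresholds strictly decreasing grid (default
#'   [default_threshold_grid()]).
#' @return a `threshold_scan`: list with `thresholds`, `partitions` (one
#'   `ssn_partition` per threshold), `refinement` (data frame `threshold`,
#'   `cluster`, `parent_threshold`, `parent_cluster`) and `summary` (long
#'   data frame `threshold`, `cluster`, `size`, `parent_cluster`), the
#'   tabular "flow" representation of how clusters split.
#' @export
threshold_scan <- function(hits, node_ids,
                           thresholds = default_threshold_grid()) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (any(diff(thresholds) >= 0))
    stop("threshold grid must be strictly decreasing")
  partitions <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    g <- build_graph(hits, node_ids, thresholds[i])
    partitions[[i]] <- connected_components(g)
  }
  names(partitions) <- format(thresholds)
  refinement <- NULL
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    p <- partitions[[i]]
    sizes <- table(unclass(p))
    parent <- rep(NA_integer_, length(sizes))
    if (i > 1) {
      pprev <- partitions[[i - 1]]
      # every member of a child cluster lies in the same parent cluster
      parent <- vapply(cluster_members(p), function(m) {
        unname(unclass(pprev)[m[1]])
      }, integer(1))
      refinement <- rbind(refinement, data.frame(
        threshold = thresholds[i],
        cluster = as.integer(names(sizes)),
        parent_threshold = thresholds[i - 1],
        parent_cluster = as.integer(parent)))
    }
    rows[[i]] <- data.frame(threshold = thresholds[i],
                            cluster = as.integer(names(sizes)),
                            size = as.integer(sizes),
                            parent_cluster = as.integer(parent))
  }
  structure(list(thresholds = thresholds, partitions = partitions,
                 refinement = refinement, summary = do.call(rbind, rows)),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  counts <- vapply(x$partitions, n_clusters, integer(1))
  cat(sprintf("<threshold_scan> %d thresholds (%g .. %g), %d sequences\n",
              length(x$thresholds), x$thresholds[1],
              x$thresholds[length(x$thresholds)],
              length(x$partitions[[1]])))
  df <- data.frame(threshold = format(x$thresholds, digits = 3),
                   components = counts, row.names = NULL)
  print.data.frame(df)
  invisible(x)
}

#' @export
summary.threshold_scan <- function(object, ...) {
  data.frame(threshold = object$thresholds,
             components = vapply(object$partitions, n_clusters, integer(1)),
             row.names = NULL)
}

#' Plot component count against threshold
#'
#' @param x a `threshold_scan`.
#' @param ... passed to [plot()].
#' @export
plot.threshold_scan <- function(x, ...) {
  s <- summary(x)
  plot(-log10(s$threshold), s$components, type = "b", pch = 16,
       xlab = expression(-log[10](E)), ylab = "connected components",
       main = "SSN threshold scan", ...)
  invisible(x)
}

#' Extract the partition at one threshold of a scan
#'
#' @param scan a `threshold_scan`.
#' @param threshold one of the scanned thresholds.
#' @return the `ssn_partition` at that threshold.
#' @export
partition_at <- function(scan, threshold) {
  i <- which(abs(log10(scan$thresholds) - log10(threshold)) < 1e-9)
  if (length(i) != 1) stop("threshold ", threshold, " not in the scan grid")
  scan$partitions[[i]]
}

#' Write the cluster-by-threshold scan summary to a TSV file
#'
#' Long format: `threshold`, `cluster`, `size`, `parent_cluster` (the
#' cluster at the adjacent looser threshold containing this one).
#'
#' @param scan a `threshold_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_scan_summary <- function(scan, path) {
  write.table(scan$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write per-sequence cluster assignments at every threshold to a TSV file
#'
#' Columns: `id`, `threshold`, `cluster`.
#'
#' @param scan a `threshold_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_partitions <- function(scan, path) {
  rows <- lapply(seq_along(scan$thresholds), function(i) {
    p <- scan$partitions[[i]]
    data.frame(id = names(p), threshold = scan$thresholds[i],
               cluster = unname(unclass(p)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
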