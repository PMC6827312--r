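# Sequence similarity networks: graphs at a threshold, connected
# components, and metanode contraction for display.

#' Build a sequence similarity network at an E-value threshold
#'
#' An edge joins an unordered pair iff the pair appears in the hit table
#' with `E <= threshold` (inclusive, so a hit exactly at a grid value is
#' kept at that grid point). All `node_ids` are present, isolated or not.
#'
#' @param hits a `hit_table`.
#' @param node_ids character vector of all sequence ids.
#' @param threshold E-value cutoff (> 0).
#' @return an `ssn_graph`: list with `nodes`, `edges` (data frame `from`,
#'   `to`, `evalue`), and `threshold`.
#' @export
build_graph <- function(hits, node_ids, threshold) {
  stopifnot(threshold > 0)
  node_ids <- sort(unique(as.character(node_ids)))
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), node_ids)
  if (length(unknown))
    stop("hit table references id(s) absent from node set: ",
         paste(head(unknown, 5), collapse = ", "))
  keep <- hits$evalue <= threshold
  edges <- data.frame(from = hits$query_id[keep], to = hits$subject_id[keep],
                      evalue = hits$evalue[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = node_ids, edges = edges, threshold = threshold),
            class = "ssn_graph")
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat(sprintf("<ssn_graph> %d nodes, %d edges at threshold %g\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

# Union-find with path halving; scales to large edge sets without recursion.
#' @noRd
union_find <- function(n_nodes, from_idx, to_idx) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from_idx)) {
    ra <- find(from_idx[e]); rb <- find(to_idx[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# Deterministic cluster labels: descending size, ties by lexicographically
# smallest member id. Assumes `nodes` is sorted.
#' @noRd
canonical_labels <- function(nodes, roots) {
  sizes <- tabulate(roots)
  first_member <- nodes[match(seq_along(sizes), roots)]
  o <- order(-sizes[unique(roots)],
             first_member[unique(roots)])
  ranked <- unique(roots)[o]
  match(roots, ranked)
}

#' Connected components of an SSN
#'
#' Components are computed with a union-find structure; cluster ids are
#' deterministic (ordered by descending size, ties broken by the
#' lexicographically smallest member id).
#'
#' @param graph an `ssn_graph`.
#' @return an `ssn_partition`: named integer vector mapping node id to
#'   cluster id, with the inducing threshold as an attribute.
#' @export
connected_components <- function(graph) {
  nodes <- graph$nodes
  if (length(nodes) == 0) {
    p <- integer(0)
  } else {
    roots <- union_find(length(nodes),
                        match(graph$edges$from, nodes),
                        match(graph$edges$to, nodes))
    p <- canonical_labels(nodes, roots)
  }
  structure(setNames(p, nodes), threshold = graph$threshold,
            class = "ssn_partition")
}

#' @export
print.ssn_partition <- function(x, ...) {
  cat(sprintf("<ssn_partition> %d nodes in %d cluster(s) at threshold %s\n",
              length(x), n_clusters(x),
              format(attr(x, "threshold") %||% NA)))
  invisible(x)
}

#' Number of clusters in a partition
#' @param partition an `ssn_partition`.
#' @return integer count.
#' @export
n_clusters <- function(partition) length(unique(unclass(partition)))

#' Members of each cluster of a partition
#' @param partition an `ssn_partition`.
#' @return named list of character id vectors, ordered by cluster id.
#' @export
cluster_members <- function(partition) {
  split(names(partition), unclass(partition))
}

#' Contract highly similar sequences into metanodes
#'
#' Nodes mutually connected at a much stricter merge threshold (default
#' `1e-85`) are merged into metanodes, found by an explicit depth-first
#' search over the sub-threshold edge set. Edges between metanodes are
#' deduplicated keeping the minimum E-value; each metanode carries its
#' member count. Contraction preserves the component structure of the
#' display graph.
#'
#' @param graph an `ssn_graph` (the display graph).
#' @param merge_threshold E-value at or below which nodes merge; must not be
#'   looser than the graph's own threshold.
#' @return list with `metanodes` (data frame `metanode`, `size`, `members`),
#'   `edges` (data frame `from`, `to`, `evalue` between metanodes) and
#'   `membership` (named vector node id -> metanode id).
#' @export
contract_metanodes <- function(graph, merge_threshold = 1e-85) {
  if (merge_threshold > graph$threshold)
    stop("merge_threshold must be at least as strict as the graph threshold")
  nodes <- graph$nodes
  sub <- graph$edges[graph$edges$evalue <= merge_threshold, , drop = FALSE]
  # adjacency over the sub-threshold edges
  adj <- vector("list", length(nodes))
  fi <- match(sub$from, nodes); ti <- match(sub$to, nodes)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  comp <- integer(length(nodes))
  cur <- 0L
  for (s in seq_along(nodes)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s                      # iterative depth-first search
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj[[v]]
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  labels <- canonical_labels(nodes, comp)
  membership <- setNames(labels, nodes)
  members <- split(nodes, labels)
  meta <- data.frame(metanode = as.integer(names(members)),
                     size = lengths(members))
  meta$members <- unname(members)
  ce <- graph$edges
  mf <- pmin(membership[ce$from], membership[ce$to])
  mt <- pmax(membership[ce$from], membership[ce$to])
  keep <- mf != mt
  ce <- data.frame(from = mf[keep], to = mt[keep],
                   evalue = ce$evalue[keep])
  o <- order(ce$from, ce$to, ce$evalue)
  ce <- ce[o, , drop = FALSE]
  ce <- ce[!duplicated(paste(ce$from, ce$to)), , drop = FALSE]
  rownames(ce) <- NULL
  list(metanodes = meta, edges = ce, membership = membership)
}

#' Export an SSN as a plain 3-column edge list
#'
#' Writes `source`, `target`, `evalue` (tab-separated, with header),
#' importable by Cytoscape. Deterministic for identical inputs.
#'
#' @param graph an `ssn_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(graph, path) {
  e <- graph$edges[order(graph$edges$from, graph$edges$to), , drop = FALSE]
  names(e) <- c("source", "target", "evalue")
  write.table(format(e, digits = 6, scientific = TRUE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an SSN in GraphML format
#'
#' Nodes carry their id; edges carry the E-value as a double attribute.
#'
#' @param graph an `ssn_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="evalue" for="edge" attr.name="evalue" attr.type="double"/>',
    '  <graph id="ssn" edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', esc(graph$nodes)), con)
  if (nrow(graph$edges))
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="evalue">%g</data></edge>',
      esc(graph$edges$from), esc(graph$edges$to), graph$edges$evalue), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
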