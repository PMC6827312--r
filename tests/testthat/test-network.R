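# SSN construction, components, threshold scan and metanode contraction.

mk_hits <- function(from, to, ev) {
  df <- data.frame(query_id = as.character(pmin(from, to)),
                   subject_id = as.character(pmax(from, to)),
                   evalue = as.numeric(ev), bit_score = -log2(as.numeric(ev)),
                   identity_pct = rep(50, length(ev)),
                   align_length = rep(100L, length(ev)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("hit_table", "data.frame"))
}

random_hits <- function(n_nodes, n_edges) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  h <- mk_hits(from[keep], to[keep], 10^-runif(sum(keep), 6, 100))
  list(nodes = nodes,
       hits = h[!duplicated(paste(h$query_id, h$subject_id)), ])
}

test_that("graph edges follow the inclusive threshold rule", {
  hits <- mk_hits(c("A", "B"), c("B", "C"), c(1e-60, 1e-30))
  g <- build_graph(hits, c("A", "B", "C"), 1e-55)
  expect_equal(nrow(g$edges), 1L)
  p <- connected_components(g)
  expect_true(same_partition(unclass(p), c(1, 1, 2)))

  g2 <- build_graph(hits, c("A", "B", "C"), 1e-25)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(n_clusters(connected_components(g2)), 1L)

  # inclusive boundary: an edge exactly at the threshold is kept
  g3 <- build_graph(hits, c("A", "B", "C"), 1e-30)
  expect_equal(nrow(g3$edges), 2L)

  # isolated nodes are retained
  empty <- mk_hits(character(), character(), numeric())
  g4 <- build_graph(empty, sprintf("x%d", 1:5), 1e-5)
  expect_equal(n_clusters(connected_components(g4)), 5L)

  expect_error(build_graph(hits, c("A", "B"), 1e-5), "absent")
})

test_that("components agree with a breadth-first oracle on random graphs", {
  set.seed(202)
  for (trial in seq_len(100)) {
    rh <- random_hits(sample(5:50, 1), sample(0:60, 1))
    g <- build_graph(rh$hits, rh$nodes, 1e-5)
    mine <- connected_components(g)
    ref <- oracle_components(rh$nodes, rh$hits$query_id, rh$hits$subject_id)
    expect_identical(unclass(mine)[rh$nodes], ref[rh$nodes])
  }
})

test_that("empty graph yields an empty partition", {
  empty <- mk_hits(character(), character(), numeric())
  g <- build_graph(empty, character(), 1e-5)
  expect_equal(length(connected_components(g)), 0L)
})

test_that("the default grid has 24 thresholds and the scan refines", {
  expect_equal(length(default_threshold_grid()), 24L)
  expect_equal(default_threshold_grid()[1], 1e-5)
  expect_equal(default_threshold_grid()[24], 1e-120)

  set.seed(303)
  rh <- random_hits(40, 80)
  scan <- threshold_scan(rh$hits, rh$nodes)
  expect_equal(length(scan$partitions), 24L)
  counts <- vapply(scan$partitions, n_clusters, integer(1))
  expect_true(all(diff(counts) >= 0))
  # each stricter cluster is contained in exactly one looser cluster
  for (i in 2:24) {
    child <- scan$partitions[[i]]
    parent <- scan$partitions[[i - 1]]
    for (m in cluster_members(child)) {
      expect_equal(length(unique(unclass(parent)[m])), 1L)
    }
  }
  # partition invariants at every threshold
  for (p in scan$partitions) {
    expect_setequal(names(p), rh$nodes)
    expect_false(anyNA(unclass(p)))
  }
  expect_error(threshold_scan(rh$hits, rh$nodes, c(1e-10, 1e-5)),
               "decreasing")
})

test_that("metanode contraction preserves component structure", {
  # triangle fully below the merge threshold collapses to one metanode
  tri <- mk_hits(c("A", "A", "B"), c("B", "C", "C"), rep(1e-90, 3))
  g <- build_graph(tri, c("A", "B", "C"), 1e-55)
  ct <- contract_metanodes(g, 1e-85)
  expect_equal(nrow(ct$metanodes), 1L)
  expect_equal(ct$metanodes$size, 3L)
  expect_equal(nrow(ct$edges), 0L)

  # chain with one strong and one weak edge
  chain <- mk_hits(c("A", "B"), c("B", "C"), c(1e-90, 1e-60))
  g2 <- build_graph(chain, c("A", "B", "C"), 1e-55)
  ct2 <- contract_metanodes(g2, 1e-85)
  expect_equal(sort(ct2$metanodes$size), c(1L, 2L))
  expect_equal(nrow(ct2$edges), 1L)

  expect_error(contract_metanodes(g2, 1e-5), "strict")

  # quotient property on random graphs: contracted components match the
  # display-graph components for any merge threshold at least as strict
  set.seed(404)
  for (trial in seq_len(100)) {
    rh <- random_hits(sample(5:40, 1), sample(0:50, 1))
    disp <- 10^-runif(1, 6, 40)
    merge <- disp * 10^-runif(1, 0, 40)
    g <- build_graph(rh$hits, rh$nodes, disp)
    ct <- contract_metanodes(g, merge)
    orig <- connected_components(g)
    # components of the contracted graph, mapped back to nodes
    meta_part <- oracle_components(as.character(unique(ct$membership)),
                                   as.character(ct$edges$from),
                                   as.character(ct$edges$to))
    lifted <- meta_part[as.character(ct$membership[rh$nodes])]
    expect_true(same_partition(unclass(orig)[rh$nodes], lifted))
  }
})

test_that("network exports are deterministic and well-formed", {
  set.seed(505)
  rh <- random_hits(15, 25)
  g <- build_graph(rh$hits, rh$nodes, 1e-5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_edge_list(g, f1); export_edge_list(g, f2)
  expect_identical(readLines(f1), readLines(f2))
  export_graphml(g, f1)
  xml <- xml2::read_xml(f1)
  expect_equal(length(xml2::xml_find_all(xml, ".//*[local-name()='node']")),
               length(rh$nodes))
  expect_equal(length(xml2::xml_find_all(xml, ".//*[local-name()='edge']")),
               nrow(g$edges))
})

test_that("components match igraph on the five-family network", {
  skip_if_not_installed("igraph")
  hits <- five_family_hits()
  ids <- five_family()$records$id
  for (thr in c(1e-5, 1e-25, 1e-55, 1e-100)) {
    g <- build_graph(hits, ids, thr)
    mine <- connected_components(g)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = g$nodes)
    ref <- igraph::components(ig)$membership
    expect_true(same_partition(unclass(mine)[g$nodes], ref[g$nodes]))
  }
})
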