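# Pairwise alignment statistics: the internal aligner against a brute-force
# oracle, Karlin-Altschul E-values, all-vs-all tables, BLAST import.

test_that("self-alignment of a homopolymer scores the matrix diagonal", {
  res <- local_align("WWWWW", "WWWWW")
  W <- oracle_blosum62()["W", "W"]
  expect_equal(res$score, 5 * W)
  expect_equal(res$identity_pct, 100)
  expect_equal(res$align_length, 5L)
  expect_error(local_align("", "WWWWW"), "empty")
})

test_that("aligner matches the brute-force affine-gap oracle on short pairs", {
  set.seed(101)
  for (trial in seq_len(60)) {
    a <- random_aa_string(sample(3:12, 1))
    b <- random_aa_string(sample(3:12, 1))
    expect_equal(local_align(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("E-values follow the closed form and its monotonicities", {
  expect_equal(compute_evalue(0, 10, 10), 100)
  expect_equal(compute_evalue(10, 100, 100), 1e4 * 2^-10)
  # doubling the database doubles E at fixed bit score
  expect_equal(compute_evalue(33, 250, 2e5), 2 * compute_evalue(33, 250, 1e5))
  # strictly decreasing in the bit score
  bits <- seq(10, 400, by = 10)
  ev <- compute_evalue(bits, 250, 5e4)
  expect_true(all(diff(ev) < 0 | ev[-1] == 1e-180))
  expect_true(all(ev > 0))
  expect_error(compute_evalue(10, 0, 10), "m, n")
})

test_that("all-vs-all evaluates unordered pairs once and respects the ceiling", {
  seqs <- vapply(1:3, function(i) random_aa_string(250), character(1))
  set.seed(7)
  identical3 <- seq_records(c("s1", "s2", "s3"), rep(random_aa_string(250), 3))
  hits <- all_vs_all(identical3)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$evalue <= 1e-100))
  expect_true(all(hits$query_id < hits$subject_id))

  # unrelated random sequences stay below the reporting ceiling
  set.seed(8)
  unrelated <- seq_records(c("u1", "u2"),
                           c(random_aa_string(250), random_aa_string(250)))
  expect_equal(nrow(all_vs_all(unrelated)), 0L)
  expect_error(all_vs_all(unrelated[1, ]), "at least 2")
})

test_that("all-vs-all is invariant to input order", {
  bundle <- generate_families(synth_config(k = 2, sizes = 6, seed = 5))
  recs <- bundle$records
  h1 <- all_vs_all(recs)
  h2 <- all_vs_all(recs[rev(seq_len(nrow(recs))), ])
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("BLAST tabular rows collapse to min-E undirected pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, ev, bs)
    paste(q, s, "95.0", "240", "12", "0", "1", "240", "1", "240", ev, bs,
          sep = "\t")
  writeLines(c(row("A", "B", "1e-60", "200"),
               row("B", "A", "1e-50", "180"),
               row("A", "A", "1e-99", "400"),
               row("B", "C", "0.0", "500"),
               row("C", "B", "0.0", "510")), path)
  hits <- parse_blast_tabular(path)
  expect_equal(nrow(hits), 2L)
  ab <- hits[hits$query_id == "A" & hits$subject_id == "B", ]
  expect_equal(ab$evalue, 1e-60)
  bc <- hits[hits$query_id == "B" & hits$subject_id == "C", ]
  expect_equal(bc$evalue, 1e-180)    # "0.0" floored
  expect_equal(bc$bit_score, 510)    # tie on E broken by max bit score

  writeLines(c(row("A", "B", "1e-60", "200"),
               paste("A", "B", "95.0", sep = "\t")), path)
  expect_error(parse_blast_tabular(path), "line 2")

  writeLines(row("A", "B", "xyz", "200"), path)
  expect_error(parse_blast_tabular(path), "unparsable")
})

test_that("internal hits exported as BLAST tabular reproduce SSN components", {
  bundle <- generate_families(synth_config(k = 3, sizes = 8, seed = 11))
  recs <- bundle$records
  internal <- all_vs_all(recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(internal, path)
  imported <- parse_blast_tabular(path)
  for (thr in 10^-seq(5, 20, by = 5)) {
    p1 <- connected_components(build_graph(internal, recs$id, thr))
    p2 <- connected_components(build_graph(imported, recs$id, thr))
    expect_true(same_partition(unclass(p1), unclass(p2)), info = thr)
  }
})
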