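# Subfamily calling rules, numbering and representative sampling.

mk_partition <- function(membership, threshold = 1e-55) {
  structure(membership, threshold = threshold, class = "ssn_partition")
}

mk_records <- function(ids, classes) {
  tax <- data.frame(kingdom = "Bacteria", phylum = "P", class = classes,
                    order = "O", family = "F", genus = "G",
                    species = ids, stringsAsFactors = FALSE)
  seq_records(ids, vapply(ids, function(i) random_aa_string(40),
                          character(1)), taxonomy = tax)
}

test_that("size and diversity rules decide subfamily status", {
  set.seed(1)
  ids19 <- sprintf("small%02d", 1:19)
  ids22 <- sprintf("div%02d", 1:22)
  recs <- mk_records(c(ids19, ids22),
                     c(rep(c("C1", "C2"), length.out = 19),
                       rep(c("C1", "C2", "C3"), length.out = 22)))
  part <- mk_partition(setNames(c(rep(2L, 19), rep(1L, 22)),
                                c(ids19, ids22)))
  suppressMessages(d <- delineate(part, recs))
  # the 19-member cluster fails the >= 20 rule despite being diverse
  expect_equal(nrow(d$subfamilies), 1L)
  expect_setequal(d$subfamilies$members[[1]], ids22)
  expect_setequal(d$nonclassified, ids19)
  expect_equal(d$classified_fraction, 22 / 41)
  # conservation: every input id is either classified or nonclassified
  expect_setequal(c(unlist(d$subfamilies$members), d$nonclassified),
                  names(part))
})

test_that("a monotaxon cluster needs an explicit override", {
  set.seed(2)
  ids <- sprintf("myco%03d", 1:346)
  recs <- mk_records(ids, rep("Actinomycetia", 346))
  part <- mk_partition(setNames(rep(1L, 346), ids))
  suppressMessages(d0 <- delineate(part, recs))
  expect_equal(nrow(d0$subfamilies), 0L)
  suppressMessages(d1 <- delineate(part, recs, overrides = 1L))
  expect_equal(nrow(d1$subfamilies), 1L)
  expect_true(d1$subfamilies$override[1])
  expect_equal(d1$classified_fraction, 1)
  expect_error(suppressMessages(delineate(part, recs, overrides = 9L)),
               "nonexistent")
})

test_that("numbering is by descending size with id tiebreak, idempotently", {
  sf <- list(list(members = sprintf("a%02d", 1:30)),
             list(members = sprintf("b%03d", 1:500)),
             list(members = sprintf("c%02d", 1:45)))
  lab <- label_subfamilies(sf)
  expect_equal(lab$size, c(500L, 45L, 30L))
  expect_equal(lab$number, 1:3)
  expect_equal(lab$members[[1]][1], "b001")

  # equal sizes: lexicographically smallest member id first
  tie <- list(list(members = c("zed", "zee")),
              list(members = c("abc", "abd")))
  expect_equal(label_subfamilies(tie)$members[[1]], c("abc", "abd"))

  # renumbering the already ordered result changes nothing
  relab <- label_subfamilies(
    lapply(seq_len(nrow(lab)), function(i) list(members = lab$members[[i]])))
  expect_equal(relab$size, lab$size)
  expect_equal(relab$members, lab$members)
})

test_that("raising min_size never increases the subfamily count", {
  set.seed(3)
  ids <- sprintf("s%03d", 1:90)
  recs <- mk_records(ids, rep(c("C1", "C2"), 45))
  part <- mk_partition(setNames(rep(1:4, c(40, 25, 15, 10)), ids))
  counts <- vapply(c(5, 10, 20, 30, 50), function(ms) {
    suppressMessages(nrow(delineate(part, recs, min_size = ms)$subfamilies))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("representative sampling is seeded and respects small subfamilies", {
  members <- sprintf("m%03d", 1:12)
  expect_identical(sample_representatives(members, n = 30), members)

  big <- sprintf("m%03d", 1:100)
  s1 <- sample_representatives(big, n = 30, seed = 99)
  s2 <- sample_representatives(big, n = 30, seed = 99)
  expect_identical(s1, s2)
  expect_equal(length(s1), 30L)
  expect_equal(anyDuplicated(s1), 0L)
  expect_true(all(s1 %in% big))
  s3 <- sample_representatives(big, n = 30, seed = 100)
  expect_equal(length(s3), 30L)
  expect_true(all(s3 %in% big))
})

test_that("membership export round-trips through TSV", {
  set.seed(4)
  ids <- sprintf("e%02d", 1:25)
  recs <- mk_records(ids, rep(c("C1", "C2"), length.out = 25))
  part <- mk_partition(setNames(c(rep(1L, 22), 2L, 2L, 3L), ids))
  suppressMessages(d <- delineate(part, recs))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_membership(d, path)
  back <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c("character", "character"))
  expect_equal(nrow(back), 25L)
  classified <- back$id[nzchar(back$subfamily)]
  expect_setequal(classified, ids[1:22])
})
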