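# Profile-HMM construction, scoring, the two-condition assignment rule and
# precision/recall bookkeeping.

test_that("a gap-free alignment of identical sequences gives point-mass emissions", {
  msa <- setNames(rep("MKTAY", 3), c("a", "b", "c"))
  m <- build_profile_hmm(msa, pseudocount = 0, calibrate = FALSE)
  expect_equal(m$M, 5L)
  for (k in 1:5) {
    expect_equal(unname(m$match_emissions[k, strsplit("MKTAY", "")[[1]][k]]),
                 1)
    expect_equal(sum(m$match_emissions[k, ]), 1)
  }
})

test_that("emission and transition rows are normalized", {
  bundle <- generate_families(synth_config(k = 1, sizes = 12,
                                           indel_rate = 0.01, seed = 21))
  msa <- build_msa(bundle$records)
  m <- build_profile_hmm(msa, calibrate = FALSE)
  expect_true(all(abs(rowSums(m$match_emissions) - 1) < 1e-9))
  tr <- m$transitions
  expect_true(all(abs(rowSums(tr[, c("MM", "MI", "MD")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, c("IM", "II")]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(tr[, c("DM", "DD")]) - 1) < 1e-9))
  expect_equal(sum(m$insert_emissions), 1, tolerance = 1e-9)
})

test_that("the gap-majority rule decides match columns", {
  # column 3 has 60% gaps: insert; column 5 has 40% gaps: match
  msa <- c("MK-AY", "MK-AY", "MKTA-", "MKTAY", "MK-A-")
  m <- build_profile_hmm(msa, calibrate = FALSE)
  expect_equal(m$M, 4L)  # columns 1, 2, 4, 5
  all_gap <- c("-M---", "--M--", "---M-")  # every column 2/3 gaps
  expect_error(build_profile_hmm(all_gap, max_gap_frac = 0.3),
               "match columns")
})

test_that("scoring requires calibration and behaves monotonically", {
  bundle <- generate_families(synth_config(k = 1, sizes = 10, seed = 22))
  msa <- build_msa(bundle$records)
  raw <- build_profile_hmm(msa, calibrate = FALSE)
  expect_error(score_sequence(bundle$records$seq[1], raw), "calibrated")

  m <- calibrate_hmm(raw, n = 100, seed = 5)
  member <- score_sequence(bundle$records$seq[1], m)
  set.seed(23)
  rand <- score_sequence(random_aa_string(250), m)
  expect_gt(member$bit_score, rand$bit_score)
  expect_lt(member$evalue, rand$evalue)

  # E-value strictly decreasing in the bit score at fixed calibration
  bits <- seq(-10, 60, by = 5)
  evs <- vapply(bits, ssnfam:::hmm_evalue, numeric(1),
                calibration = m$calibration, search_space = 10)
  expect_true(all(diff(evs) <= 0))
  informative <- evs < 10  # below the saturated p = 1 region
  expect_true(all(diff(evs[informative]) < 0))
})

test_that("forward log-odds never falls below Viterbi log-odds", {
  bundle <- generate_families(synth_config(k = 2, sizes = 8, seed = 24))
  msa <- build_msa(bundle$records[1:8, ])
  m <- build_profile_hmm(msa, calibrate = FALSE)
  m <- calibrate_hmm(m, n = 50, seed = 3)
  set.seed(25)
  probes <- c(bundle$records$seq[c(1, 9, 12)],
              random_aa_string(180), random_aa_string(400))
  for (s in probes) {
    fw <- score_sequence(s, m, algorithm = "forward")$bit_score
    vit <- score_sequence(s, m, algorithm = "viterbi")$bit_score
    expect_gte(fw, vit - 1e-9)
  }
})

test_that("a family consensus outscores its shuffles", {
  bundle <- generate_families(synth_config(k = 1, sizes = 15, seed = 26))
  msa <- build_msa(bundle$records)
  m <- calibrate_hmm(build_profile_hmm(msa, calibrate = FALSE),
                     n = 100, seed = 4)
  cons <- apply(m$match_emissions, 1, function(p)
    colnames(m$match_emissions)[which.max(p)])
  cons <- paste(cons, collapse = "")
  own <- score_sequence(cons, m)$bit_score
  set.seed(27)
  shuffled <- vapply(seq_len(200), function(i) {
    s <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    score_sequence(s, m)$bit_score
  }, numeric(1))
  expect_gt(own, quantile(shuffled, 0.99))
})

test_that("the two-condition assignment rule reproduces its worked examples", {
  mk <- function(e_best, e_second) {
    data.frame(id = "p", best_model = "s1", e_best = e_best,
               e_second = e_second, bit_best = 100)
  }
  rule <- ssnfam:::apply_assignment_rule
  # (i) and (ii) both satisfied: ratio 1e15
  expect_equal(rule(mk(1e-40, 1e-25), 1e-30, 1e10), "s1")
  # (ii) fails: ratio 1e5
  expect_true(is.na(rule(mk(1e-40, 1e-35), 1e-30, 1e10)))
  # (i) fails regardless of the second hit
  expect_true(is.na(rule(mk(1e-20, 1e-80), 1e-30, 1e10)))
  # sole hit: second E treated as infinite
  expect_equal(rule(mk(1e-40, Inf), 1e-30, 1e10), "s1")
  # remainder model wins: no subfamily prediction
  rem <- mk(1e-60, 1e-20); rem$best_model <- "remainder"
  expect_true(is.na(rule(rem, 1e-30, 1e10)))
})

test_that("assignment-rule monotonicity in ceiling and fold", {
  set.seed(28)
  df <- data.frame(id = sprintf("p%02d", 1:40),
                   best_model = sample(c("s1", "s2"), 40, TRUE),
                   e_best = 10^-runif(40, 5, 80),
                   e_second = 10^-runif(40, 0, 50))
  df$e_second <- pmax(df$e_second, df$e_best)
  rule <- ssnfam:::apply_assignment_rule
  n_pred <- function(ceiling, fold) sum(!is.na(rule(df, ceiling, fold)))
  expect_true(all(diff(vapply(c(1e-60, 1e-40, 1e-20, 1e-5),
                              n_pred, numeric(1), fold = 1e10)) >= 0))
  expect_true(all(diff(vapply(c(1e2, 1e6, 1e10, 1e14),
                              n_pred, numeric(1),
                              ceiling = 1e-20)) <= 0))
})

test_that("precision/recall counting matches the hand-enumerated example", {
  # reference: p1->s1, p2->s1, p3->s2, p4 unassigned
  # predictions: p1->s1 (TP), p2->s2 (FP), p3 none (FN), p4->s1 (FP)
  asg <- data.frame(
    id = c("p1", "p2", "p3", "p4"),
    best_model = c("s1", "s2", "remainder", "s1"),
    e_best = c(1e-50, 1e-50, 1e-50, 1e-50),
    e_second = c(Inf, Inf, Inf, Inf),
    bit_best = 100, stringsAsFactors = FALSE)
  reference <- c(p1 = "s1", p2 = "s1", p3 = "s2", p4 = NA)
  pr <- evaluate_library(asg, reference, cutoffs = 1e-30)
  expect_equal(pr$tp, 1L)
  expect_equal(pr$fp, 2L)
  expect_equal(pr$fn, 1L)
  expect_equal(pr$precision, 1 / 3)
  expect_equal(pr$recall, 1 / 2)

  # perfect predictions give precision = recall = 1
  perfect <- data.frame(
    id = c("p1", "p2", "p3", "p4"),
    best_model = c("s1", "s1", "s2", "remainder"),
    e_best = 1e-50, e_second = Inf, bit_best = 100,
    stringsAsFactors = FALSE)
  pr2 <- evaluate_library(perfect, reference, cutoffs = 1e-30)
  expect_equal(pr2$precision, 1)
  expect_equal(pr2$recall, 1)

  # zero predictions: recall 0, precision 1 by convention, flagged
  none <- perfect; none$e_best <- 1e-5
  pr3 <- evaluate_library(none, reference, cutoffs = 1e-30)
  expect_equal(pr3$recall, 0)
  expect_equal(pr3$precision, 1)
  expect_true(pr3$vacuous_precision)

  expect_error(evaluate_library(asg, reference[1:2], cutoffs = 1e-30),
               "absent")
})

test_that("an HMM library survives JSON-lines serialization", {
  bundle <- generate_families(synth_config(k = 2, sizes = 10, seed = 29))
  membership <- setNames(bundle$truth$subfamily, bundle$truth$id)
  lib <- build_hmm_library(bundle$records, membership, n_calib = 60)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_hmm_library(lib, path)
  back <- read_hmm_library(path)
  expect_equal(length(back$models), 3L)  # 2 subfamilies + remainder
  expect_setequal(names(back$models), c("1", "2", "remainder"))
  s <- bundle$records$seq[1]
  for (nm in names(lib$models)) {
    expect_equal(score_sequence(s, back$models[[nm]], 3)$bit_score,
                 score_sequence(s, lib$models[[nm]], 3)$bit_score,
                 tolerance = 1e-12)
  }
})
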