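test_that("stage 1 applies the published NFS/FIB-4 rule thresholds", {
  expect_equal(as.character(stage1_classify(-2.0, 1.0)), "ruled_out")
  expect_equal(as.character(stage1_classify(1.0, 3.0)), "ruled_in")
  expect_equal(as.character(stage1_classify(0.0, 2.0)), "grey")
  # boundaries: rule-out inclusive, rule-in strict
  expect_equal(as.character(stage1_classify(-1.455, 1.3)), "ruled_out")
  expect_equal(as.character(stage1_classify(0.676, 2.68)), "grey")
  expect_equal(as.character(stage1_classify(0.677, 2.67)), "grey")
  # both conditions are required jointly
  expect_equal(as.character(stage1_classify(-2.0, 1.4)), "grey")
  expect_warning(s <- stage1_classify(NA, 1.0), "grey")
  expect_equal(as.character(s), "grey")
})

test_that("stage 2 combines TyG and VAI under the chosen rule", {
  expect_equal(as.character(stage2_classify(5.7, 6.5)), "ruled_in")
  expect_equal(as.character(stage2_classify(2.0, 1.0)), "ruled_out")
  expect_equal(as.character(stage2_classify(4.0, 3.0)), "unclassified")
  # boundaries mirror stage 1: rule-out inclusive, rule-in strict
  expect_equal(as.character(stage2_classify(2.65, 1.67)), "ruled_out")
  expect_equal(as.character(stage2_classify(5.61, 6.5)), "unclassified")
  # under "either" one score suffices
  expect_equal(as.character(stage2_classify(5.7, 3.0, combination = "either")),
               "ruled_in")
  # conflicting signals are never classified
  expect_equal(as.character(stage2_classify(5.7, 1.0, combination = "either")),
               "unclassified")
})

test_that("run_cascade refines only the grey zone", {
  panel <- data.frame(subject_id = c("a", "b", "c", "d"),
                      nfs = c(-2, 1, 0, 0), fib4 = c(1, 3, 2, 2),
                      tyg = c(9, 9, 6, 4), vai = c(9, 9, 7, 3))
  res <- run_cascade(panel)
  expect_equal(as.character(res$label),
               c("ruled_out", "ruled_in", "ruled_in", "unclassified"))
  expect_equal(res$stage, c(1L, 1L, 2L, NA))
  # stage-1 classified subjects keep their label regardless of TyG/VAI
  expect_equal(res$inputs_used[1:2], c("nfs+fib4", "nfs+fib4"))
  # empty input -> empty output
  expect_identical(nrow(run_cascade(panel[0, ])), 0L)
  # worst case: all grey, stage 2 resolves nothing
  grey <- data.frame(subject_id = 1:5, nfs = 0, fib4 = 2, tyg = 4, vai = 3)
  expect_true(all(run_cascade(grey)$label == "unclassified"))
})

test_that("evaluate_cascade counts correctness against the TE reference", {
  panel <- data.frame(subject_id = 1:4, nfs = c(-2, -2, 1, 0),
                      fib4 = c(1, 1, 3, 2), tyg = c(4, 4, 4, 4),
                      vai = c(3, 3, 3, 3))
  ref <- data.frame(subject_id = 1:4,
                    fibrosis_stage = stage_fibrosis(c(5, 14, 14, 9)))
  rep <- evaluate_cascade(run_cascade(panel), ref)
  expect_equal(rep$n_stage1_ruled_out_correct, 1)  # 1 of 2 rule-outs correct
  expect_equal(rep$n_stage1_ruled_out, 2)
  expect_equal(rep$n_stage1_ruled_in_correct, 1)   # 1 of 1 rule-ins correct
  expect_equal(rep$pct_unclassified_after, 25)
  # id mismatch is an error naming the subject
  expect_error(evaluate_cascade(run_cascade(panel), ref[-2, ]), "2")
})

test_that("report counts partition the cohort and match brute-force recounts", {
  set.seed(99)
  n <- 200
  panel <- data.frame(subject_id = seq_len(n),
                      nfs = rnorm(n, -0.5, 1.5), fib4 = rlnorm(n, 0.4, 0.6),
                      tyg = rnorm(n, 4.6, 1.2), vai = rlnorm(n, 1, 0.8))
  ref <- data.frame(subject_id = seq_len(n),
                    severe_fibrosis = runif(n) < 0.3)
  res <- run_cascade(panel)
  rep <- evaluate_cascade(res, ref)
  expect_equal(rep$n_stage1_ruled_out + rep$n_stage1_ruled_in + rep$n_grey,
               rep$n_total)
  expect_lte(rep$n_stage2_classified, rep$n_grey)
  expect_lte(rep$pct_unclassified_after, rep$pct_unclassified_before)
  # independent recount straight from the score table
  co <- default_cutoffs()
  out1 <- panel$nfs <= co$nfs$rule_out & panel$fib4 <= co$fib4$rule_out
  in1 <- panel$nfs > co$nfs$rule_in & panel$fib4 > co$fib4$rule_in
  grey <- !out1 & !in1
  expect_equal(rep$n_stage1_ruled_out, sum(out1))
  expect_equal(rep$n_stage1_ruled_in, sum(in1))
  expect_equal(rep$n_grey, sum(grey))
  in2 <- grey & panel$tyg > co$tyg$rule_in & panel$vai > co$vai$rule_in
  out2 <- grey & panel$tyg <= co$tyg$rule_out & panel$vai <= co$vai$rule_out
  expect_equal(rep$n_stage2_classified, sum(in2) + sum(out2))
  expect_equal(rep$n_stage2_correct,
               sum(in2 & ref$severe_fibrosis) + sum(out2 & !ref$severe_fibrosis))
  expect_equal(rep$n_stage1_ruled_out_correct, sum(out1 & !ref$severe_fibrosis))
})

test_that("perfect and degenerate classifiers give the expected fractions", {
  # perfect: every classified subject matches the reference
  panel <- data.frame(subject_id = 1:6, nfs = c(rep(-2, 3), rep(1, 3)),
                      fib4 = c(rep(1, 3), rep(3, 3)), tyg = 4, vai = 3)
  ref <- data.frame(subject_id = 1:6, severe_fibrosis = rep(c(FALSE, TRUE), each = 3))
  rep <- evaluate_cascade(run_cascade(panel), ref)
  expect_equal(rep$pct_stage1_ruled_out_correct, 100)
  expect_equal(rep$pct_stage1_ruled_in_correct, 100)
  expect_equal(rep$n_unclassified_after, 0)
  # all unclassified: before and after both 100%
  grey <- data.frame(subject_id = 1:4, nfs = 0, fib4 = 2, tyg = 4, vai = 3)
  ref2 <- data.frame(subject_id = 1:4, severe_fibrosis = FALSE)
  rep2 <- evaluate_cascade(run_cascade(grey), ref2)
  expect_equal(rep2$pct_unclassified_before, 100)
  expect_equal(rep2$pct_unclassified_after, 100)
})

test_that("the built-in example cohort reproduces its designed margins", {
  ex <- example_cascade_cohort()
  expect_identical(nrow(ex$panel), 114L)
  rep <- evaluate_cascade(run_cascade(ex$panel), ex$reference)
  expect_equal(rep$n_stage1_ruled_out, 51)
  expect_equal(rep$n_stage1_ruled_in, 21)
  expect_equal(rep$n_grey, 42)
  expect_equal(rep$n_stage2_classified, 12)
  expect_equal(rep$n_stage2_correct, 9)
})
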