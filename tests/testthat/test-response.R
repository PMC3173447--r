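test_that("summarize_roi takes medians over fitted voxels", {
  expect_equal(unname(summarize_roi(manual_param_map(0.42))["ktrans"]), 0.42)
  expect_equal(unname(summarize_roi(manual_param_map(c(0.1, 0.2, 0.4)))["ktrans"]),
               0.2)
  # equals a brute-force sort median on a two-region lesion
  vals <- c(rep(0.1, 9), rep(0.4, 12))
  srt <- sort(vals)
  expect_equal(unname(summarize_roi(manual_param_map(vals))["ktrans"]),
               srt[(length(srt) + 1) / 2])
  empty <- manual_param_map(0.1)
  empty$voxels$fitted <- FALSE
  expect_error(summarize_roi(empty), "no fitted voxels")
})

test_that("percent change follows the clinical convention", {
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_equal(percent_change(0.5, 0.25), -50)
  expect_equal(percent_change(0.1, 0.293), 193)  # a Ve increase under treatment
  expect_error(percent_change(0, 1), "positive")
  expect_equal(round_percent(c(72.5, -72.5, 92.3)), c(73, -73, 92))
})

test_that("cutoff boundary is inclusive toward responder", {
  expect_equal(as.character(classify_by_cutoff(-72, -72)), "responder")
  expect_equal(as.character(classify_by_cutoff(193, -72)), "non_responder")
  expect_equal(as.character(classify_by_cutoff(-100, -72)), "responder")
  expect_equal(as.character(classify_by_cutoff(-84, -84)), "responder")
})

test_that("classification is monotone in the cutoff", {
  set.seed(5)
  change <- runif(50, -100, 200)
  for (cuts in list(c(-72, -87), c(-20, -50), c(0, -99))) {
    hi <- classify_by_cutoff(change, max(cuts))
    lo <- classify_by_cutoff(change, min(cuts))
    # lowering the cutoff never converts a non-responder call to responder
    expect_true(all(lo[hi == "non_responder"] == "non_responder"))
  }
})

test_that("the joint rule flags non-response when either parameter fails", {
  expect_equal(as.character(classify_combined(-98, -38)), "non_responder")
  expect_equal(as.character(classify_combined(-100, -94)), "responder")
  expect_equal(as.character(classify_combined(-100, -100)), "responder")
  expect_equal(as.character(classify_combined(-50, -94)), "non_responder")
})

test_that("the WHO size rule uses -50% inclusive", {
  expect_equal(as.character(who_size_classify(c(-50, 57, -100))),
               c("responder", "non_responder", "responder"))
})

test_that("diagnostic performance reproduces the reference operating point", {
  tab <- load_table3()
  truth <- nonresponder_truth(tab$sataloff_grade)
  perf <- diagnostic_performance(
    classify_by_cutoff(tab$ve_change_measured, -72), truth, "non_responder")
  expect_equal(c(perf$tp, perf$fn, perf$fp, perf$tn), c(8, 3, 1, 12))
  expect_equal(perf$sensitivity, 73)
  expect_equal(perf$specificity, 92)
  expect_equal(perf$ppv, 89)
  expect_equal(perf$npv, 80)
  expect_equal(perf$accuracy, 83)
})

test_that("perfect prediction yields 100% rates with CI upper bound 100", {
  truth <- factor(rep(c("a", "b"), c(6, 8)))
  perf <- diagnostic_performance(truth, truth, positive = "b")
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_equal(perf$accuracy, 100)
  expect_equal(perf$sensitivity_ci[2], 100)
})

test_that("rates match brute-force confusion counting on a large random fixture", {
  set.seed(99)
  truth <- sample(c("pos", "neg"), 1000, replace = TRUE)
  pred <- sample(c("pos", "neg"), 1000, replace = TRUE)
  perf <- diagnostic_performance(pred, truth, positive = "pos")
  tp <- sum(pred == "pos" & truth == "pos")
  fp <- sum(pred == "pos" & truth == "neg")
  fn <- sum(pred == "neg" & truth == "pos")
  tn <- sum(pred == "neg" & truth == "neg")
  expect_equal(c(perf$tp, perf$fp, perf$fn, perf$tn), c(tp, fp, fn, tn))
  expect_equal(unname(perf$rates["sensitivity"]), tp / (tp + fn))
  expect_equal(unname(perf$rates["accuracy"]), (tp + tn) / 1000)
  # accuracy decomposition holds by construction
  expect_equal(perf$rates[["accuracy"]],
               (perf$rates[["sensitivity"]] * (tp + fn) +
                  perf$rates[["specificity"]] * (tn + fp)) / 1000)
})

test_that("degenerate truth vectors are rejected", {
  expect_error(diagnostic_performance(c("a", "b"), c("a", "a"), "a"),
               "both classes")
  expect_error(diagnostic_performance("a", c("a", "b"), "a"), "length")
})

test_that("Clopper-Pearson intervals reproduce the printed bounds", {
  truth <- factor(rep(c("neg", "pos"), c(13, 11)))
  pred <- factor(c(rep("neg", 12), "pos", rep("pos", 8), rep("neg", 3)))
  perf <- diagnostic_performance(pred, truth, positive = "pos")
  expect_equal(c(perf$tp, perf$fn), c(8, 3))
  expect_equal(perf$sensitivity_ci, c(39, 94))   # 8/11
  expect_equal(c(perf$tn, perf$fp), c(12, 1))
  expect_equal(perf$specificity_ci, c(64, 100))  # 12/13
})

test_that("exact binomial intervals cover at the nominal level", {
  set.seed(31)
  n <- 11
  for (p in c(0.1, 0.5, 0.9)) {
    k <- rbinom(1000, n, p)
    covered <- vapply(k, function(ki) {
      ci <- binom.test(ki, n)$conf.int
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  }
})
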