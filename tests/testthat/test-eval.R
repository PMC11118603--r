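test_that("confusion counts tally exactly", {
  cc <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(2L, 1L, 0L, 0L))
  flipped <- confusion_counts(c(0, 1, 0), c(1, 0, 1))
  expect_equal(c(flipped$TP, flipped$TN), c(0L, 0L))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
  # brute-force oracle on a random 1,000-pair case
  set.seed(14)
  pred <- sample(0:1, 1000, replace = TRUE)
  truth <- sample(0:1, 1000, replace = TRUE, prob = c(0.9, 0.1))
  cc <- confusion_counts(pred, truth)
  tally <- table(factor(pred, 0:1), factor(truth, 0:1))
  expect_equal(cc$TP, unname(tally["1", "1"]))
  expect_equal(cc$TN, unname(tally["0", "0"]))
  expect_equal(cc$FP, unname(tally["1", "0"]))
  expect_equal(cc$FN, unname(tally["0", "1"]))
})

test_that("the four metrics evaluate their defining ratios as percentages", {
  r <- eval_metrics(confusion_counts(c(rep(1, 9), rep(0, 1), rep(1, 2), rep(0, 88)),
                                     c(rep(1, 10), rep(0, 90))))
  expect_equal(r$accuracy, 97)
  expect_equal(r$sensitivity, 90)
  expect_equal(r$specificity, 100 * 88 / 90, tolerance = 1e-12)
  expect_equal(round(r$specificity, 2), 97.78)
  expect_equal(r$balanced_accuracy, (90 + 100 * 88 / 90) / 2)
  expect_equal(round(r$balanced_accuracy, 2), 93.89)
  perfect <- evaluate_predictions(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(perfect$accuracy, perfect$sensitivity,
                 perfect$specificity, perfect$balanced_accuracy),
               rep(100, 4))
})

test_that("an always-negative predictor scores 0 / 100 / BA 50", {
  truth <- c(rep(1, 13), rep(0, 87))
  r <- evaluate_predictions(rep(0, 100), truth)
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 100)
  expect_equal(r$balanced_accuracy, 50)
  expect_equal(r$accuracy, 87)
})

test_that("undefined ratios surface as NaN with a warning, never as zero", {
  expect_warning(r <- eval_metrics(confusion_counts(rep(0, 10), rep(0, 10))),
                 "sensitivity")
  expect_true(is.nan(r$sensitivity))
  expect_equal(r$specificity, 100)
  expect_error(eval_metrics(confusion_counts(integer(0), integer(0))),
               "zero")
})

test_that("the zero rule reflects prevalence and always has BA 50 on mixed labels", {
  truth <- c(rep(1L, 806), rep(0L, 9194))  # 8.06% positive
  zr <- zero_rule(truth)
  expect_equal(zr$accuracy, 91.94)
  expect_equal(zr$sensitivity, 0)
  expect_equal(zr$specificity, 100)
  expect_equal(zr$balanced_accuracy, 50)
  set.seed(3)
  for (p in c(0.02, 0.2, 0.45)) {
    truth <- as.integer(runif(400) < p)
    expect_equal(zero_rule(truth)$balanced_accuracy, 50)
  }
  expect_warning(all_neg <- zero_rule(rep(0L, 20)), "sensitivity")
  expect_equal(all_neg$accuracy, 100)
  expect_true(is.nan(all_neg$sensitivity))
  expect_error(zero_rule(integer(0)), "empty")
})

test_that("metric identities hold for random confusion tables", {
  set.seed(6)
  for (i in 1:25) {
    tp <- sample(0:50, 1); fn <- sample(1:50, 1)
    fp <- sample(0:50, 1); tn <- sample(1:50, 1)
    truth <- c(rep(1, tp + fn), rep(0, fp + tn))
    pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
    r <- evaluate_predictions(pred, truth)
    expect_equal(r$balanced_accuracy, (r$sensitivity + r$specificity) / 2)
    prev <- (tp + fn) / length(truth)
    expect_equal(r$accuracy, prev * r$sensitivity + (1 - prev) * r$specificity)
  }
})

test_that("evaluation reports round-trip through CSV and JSON", {
  r <- evaluate_predictions(c(1, 0, 0, 1, 0), c(1, 1, 0, 1, 0),
                            model = "gru", partition = "test", k_early = 2L)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_eval_report(r, path)
    back <- read_eval_report(path)
    expect_equal(back$accuracy, r$accuracy)
    expect_equal(back$sensitivity, r$sensitivity)
    expect_equal(back$balanced_accuracy, r$balanced_accuracy)
    expect_equal(back$TP, r$counts$TP)
    expect_equal(back$k_early, 2L)
  }
})
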