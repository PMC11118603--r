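# Confusion counts, the four headline metrics, zero-rule baselines, and
# the early-detection sweep.

#' Confusion counts for binary predictions
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with fields `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (!all(predicted %in% 0:1) || !all(truth %in% 0:1))
    stop("labels must be 0 or 1")
  structure(list(TP = sum(predicted == 1L & truth == 1L),
                 FN = sum(predicted == 0L & truth == 1L),
                 FP = sum(predicted == 1L & truth == 0L),
                 TN = sum(predicted == 0L & truth == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("          predicted+  predicted-\n"))
  cat(sprintf("  true+   %9d  %9d\n", x$TP, x$FN))
  cat(sprintf("  true-   %9d  %9d\n", x$FP, x$TN))
  invisible(x)
}

#' Accuracy, sensitivity, specificity and balanced accuracy
#'
#' Computes, as percentages:
#' accuracy = (TP+TN)/(TP+FN+FP+TN), sensitivity = TP/(TP+FN),
#' specificity = TN/(FP+TN), and balanced accuracy = their arithmetic
#' mean. A ratio with an empty denominator (a class absent from the
#' truth) is reported as `NaN` with a warning, never silently zero.
#'
#' @param counts a [confusion_counts()] object.
#' @param model,partition,k_early optional provenance fields carried into
#'   the report.
#' @return object of class `eval_report`.
#' @export
eval_metrics <- function(counts, model = NA_character_,
                         partition = NA_character_, k_early = NA_integer_) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FN + counts$FP + counts$TN
  if (n == 0) stop("all confusion counts are zero")
  sens <- if (counts$TP + counts$FN > 0) {
    100 * counts$TP / (counts$TP + counts$FN)
  } else {
    warning("no positive samples: sensitivity is undefined (NaN)")
    NaN
  }
  spec <- if (counts$FP + counts$TN > 0) {
    100 * counts$TN / (counts$FP + counts$TN)
  } else {
    warning("no negative samples: specificity is undefined (NaN)")
    NaN
  }
  structure(list(accuracy = 100 * (counts$TP + counts$TN) / n,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 counts = counts, model = model, partition = partition,
                 k_early = k_early),
            class = "eval_report")
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: tallies the confusion counts and computes the
#' four metrics.
#'
#' @param predicted,truth 0/1 vectors.
#' @inheritParams eval_metrics
#' @return an `eval_report`.
#' @export
evaluate_predictions <- function(predicted, truth, model = NA_character_,
                                 partition = NA_character_,
                                 k_early = NA_integer_) {
  eval_metrics(confusion_counts(predicted, truth), model, partition, k_early)
}

#' @export
print.eval_report <- function(x, ...) {
  tag <- if (!is.na(x$model)) paste0(" [", x$model,
                                     if (!is.na(x$partition))
                                       paste0(", ", x$partition), "]") else ""
  cat(sprintf("<eval_report>%s\n", tag))
  cat(sprintf("  accuracy %6.2f  sensitivity %6.2f  specificity %6.2f  balanced accuracy %6.2f\n",
              x$accuracy, x$sensitivity, x$specificity,
              x$balanced_accuracy))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$counts$TP, x$counts$FN,
              x$counts$FP, x$counts$TN))
  invisible(x)
}

#' Zero-rule (constant majority class) baseline
#'
#' Metrics of the predictor that always outputs the majority class. With
#' negatives in the majority: accuracy equals the negative prevalence,
#' sensitivity 0, specificity 100, balanced accuracy 50.
#'
#' @param truth 0/1 label vector.
#' @return an `eval_report` for the constant predictor.
#' @export
zero_rule <- function(truth) {
  if (!length(truth)) stop("empty label set")
  truth <- as.integer(truth)
  majority <- if (sum(truth == 1L) > sum(truth == 0L)) 1L else 0L
  if (majority == 1L)
    warning("positives are the majority class; zero rule predicts positive")
  evaluate_predictions(rep(majority, length(truth)), truth,
                       model = "zero-rule")
}

#' Serialize / read back an evaluation report
#'
#' @param report an `eval_report` (or data frame of sweep rows).
#' @param path output path; `.json` or `.csv` chosen by extension.
#' @return `write_eval_report()` returns `path` invisibly;
#'   `read_eval_report()` the parsed object.
#' @export
write_eval_report <- function(report, path) {
  if (inherits(report, "eval_report")) {
    report <- report_as_row(report)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    read.csv(path)
  }
}

report_as_row <- function(r) {
  data.frame(model = r$model, partition = r$partition, k_early = r$k_early,
             accuracy = r$accuracy, sensitivity = r$sensitivity,
             specificity = r$specificity,
             balanced_accuracy = r$balanced_accuracy,
             TP = r$counts$TP, FN = r$counts$FN, FP = r$counts$FP,
             TN = r$counts$TN, stringsAsFactors = FALSE)
}

#' Early-detection sweep over lookahead offsets
#'
#' For each `k` in `k_values`: relabel the recordings' windows `k`
#' windows early, re-split with the same seed policy, retrain the
#' class-weighted GRU selected by validation balanced accuracy, and
#' evaluate on the test partition. Each k is a full retraining — a k = 0
#' model is never reused with shifted labels.
#'
#' @param recordings list of [eeg_bipolar()] recordings (already
#'   montaged), or a directory of EDF files.
#' @param k_values integer lookahead offsets, each in `[0, 9]`.
#' @param seed seed for split, initialization and shuffling.
#' @param epochs,lr,batch_size training configuration per k.
#' @param arch,select,weights forwarded to [fit_ied()].
#' @return data frame with one row per k: the four test metrics plus the
#'   per-k zero-rule accuracy and balanced accuracy.
#' @export
early_detection_sweep <- function(recordings, k_values = 0:9, seed = 1,
                                  epochs = 30, lr = 1e-4, batch_size = 512,
                                  arch = "gru", select = "ba",
                                  weights = "auto") {
  stopifnot(all(k_values >= 0), all(k_values <= 9))
  rows <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    row <- tryCatch({
      pooled <- if (is.character(recordings)) {
        preprocess_dir(recordings, k_early = k)
      } else {
        bind_windows(lapply(recordings, make_windows, k_early = k))
      }
      split <- stratified_split(pooled$labels, seed = seed)
      fit <- fit_ied(pooled, arch = arch, split = split, weights = weights,
                     epochs = epochs, lr = lr, batch_size = batch_size,
                     select = select, seed = seed)
      test_x <- pooled$x[, , split$test, drop = FALSE]
      pred <- predict(fit, test_x)
      rep_k <- evaluate_predictions(pred, pooled$labels[split$test],
                                    model = arch, partition = "test",
                                    k_early = k)
      zr <- zero_rule(pooled$labels[split$test])
      data.frame(k = k, accuracy = rep_k$accuracy,
                 sensitivity = rep_k$sensitivity,
                 specificity = rep_k$specificity,
                 balanced_accuracy = rep_k$balanced_accuracy,
                 zero_rule_accuracy = zr$accuracy,
                 zero_rule_balanced_accuracy = zr$balanced_accuracy,
                 failed = FALSE)
    }, error = function(err) {
      warning("sweep failed at k = ", k, ": ", conditionMessage(err))
      data.frame(k = k, accuracy = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, balanced_accuracy = NA_real_,
                 zero_rule_accuracy = NA_real_,
                 zero_rule_balanced_accuracy = NA_real_, failed = TRUE)
    })
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
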