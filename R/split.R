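# Stratified train/validation/test partitioning and class weights.

#' Stratified 64/16/20 split
#'
#' Within each class, indices are shuffled with the seeded generator and
#' divided 8:2 into pseudo-train and test; the pseudo-train part is then
#' divided 8:2 into train and validation, so the final shares are 64%,
#' 16% and 20% and every partition preserves the class proportions.
#' Rounding is deterministic: the smaller share of each cut takes the
#' floor and the remainder goes to the larger, slightly favouring the
#' training set.
#'
#' @param labels 0/1 integer vector over the pooled windows.
#' @param seed integer seed for the per-class shuffles.
#' @return object of class `split_dataset`: list with integer index
#'   vectors `train`, `validation`, `test`, a `class_counts` matrix
#'   (partition x class), and `seed`.
#' @export
stratified_split <- function(labels, seed = 1) {
  if (!length(labels)) stop("cannot split an empty label set")
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("both classes must be present to stratify the split")
  small <- table(labels)[table(labels) < 5]
  if (length(small))
    warning("class(es) with fewer than 5 members: some partition may be empty")

  set.seed(seed)
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_test <- floor(0.2 * n)
    pseudo <- n - n_test
    n_val <- floor(0.2 * pseudo)
    n_train <- pseudo - n_val
    parts$train <- c(parts$train, idx[seq_len(n_train)])
    parts$validation <- c(parts$validation, idx[n_train + seq_len(n_val)])
    parts$test <- c(parts$test, idx[n_train + n_val + seq_len(n_test)])
  }
  parts <- lapply(parts, sort)
  counts <- sapply(parts, function(ix) {
    vapply(classes, function(cl) sum(labels[ix] == cl), 0L)
  })
  counts <- t(counts)
  colnames(counts) <- as.character(classes)
  structure(list(train = parts$train, validation = parts$validation,
                 test = parts$test, class_counts = counts,
                 seed = as.integer(seed)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  n <- sum(x$class_counts)
  cat(sprintf("<split_dataset> %d samples: train %d (%.1f%%), validation %d (%.1f%%), test %d (%.1f%%); seed %d\n",
              n, length(x$train), 100 * length(x$train) / n,
              length(x$validation), 100 * length(x$validation) / n,
              length(x$test), 100 * length(x$test) / n, x$seed))
  print(x$class_counts)
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' `weight_i = (total training count) / (training count of class i)`,
#' with no normalization, computed from the training partition only. Each
#' class then contributes equal total weight to the loss:
#' `weight_i * n_i` is the same for both classes.
#'
#' @param train_labels 0/1 labels of the training partition.
#' @return named numeric vector of class weights (`"0"`, `"1"`).
#' @export
class_weights <- function(train_labels) {
  train_labels <- as.integer(train_labels)
  counts <- c(`0` = sum(train_labels == 0L), `1` = sum(train_labels == 1L))
  if (any(counts == 0))
    stop("both classes must be present in the training partition")
  total <- sum(counts)
  total / counts
}

#' Write a split manifest as JSON
#'
#' @param split a `split_dataset`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "split_dataset"))
  manifest <- list(seed = split$seed,
                   class_counts = apply(split$class_counts, 1, as.list),
                   train = split$train, validation = split$validation,
                   test = split$test)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
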