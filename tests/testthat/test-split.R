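test_that("the 125/875 example splits to the exact 64/16/20 counts", {
  labels <- c(rep(1L, 125), rep(0L, 875))
  s <- stratified_split(labels, seed = 4)
  cc <- s$class_counts
  expect_equal(unname(cc["train", c("1", "0")]), c(80L, 560L))
  expect_equal(unname(cc["validation", c("1", "0")]), c(20L, 140L))
  expect_equal(unname(cc["test", c("1", "0")]), c(25L, 175L))
  expect_length(s$train, 640L)
  expect_length(s$validation, 160L)
  expect_length(s$test, 200L)
})

test_that("partitions are disjoint, exhaustive, and seed-deterministic", {
  set.seed(10)
  labels <- as.integer(runif(517) < 0.12)
  a <- stratified_split(labels, seed = 1)
  b <- stratified_split(labels, seed = 1)
  expect_identical(a, b)
  all_idx <- c(a$train, a$validation, a$test)
  expect_equal(sort(all_idx), seq_along(labels))
  expect_equal(anyDuplicated(all_idx), 0L)
  c2 <- stratified_split(labels, seed = 2)
  expect_equal(lengths(c2[c("train", "validation", "test")]),
               lengths(a[c("train", "validation", "test")]))
  expect_false(identical(c2$train, a$train))
})

test_that("proportions and stratification hold across sizes and prevalences", {
  set.seed(77)
  for (n in c(97, 430, 1003)) {
    for (p in c(0.08, 0.3)) {
      labels <- c(rep(1L, max(6, round(p * n))),
                  rep(0L, n - max(6, round(p * n))))
      labels <- sample(labels)
      s <- stratified_split(labels, seed = 3)
      # floor-to-train rounding shifts each partition by at most one
      # window per class per cut
      expect_lt(abs(length(s$train) / n - 0.64), 4 / n + 1e-9)
      expect_lt(abs(length(s$validation) / n - 0.16), 2 / n + 1e-9)
      expect_lt(abs(length(s$test) / n - 0.20), 2 / n + 1e-9)
      prev <- mean(labels)
      for (part in list(s$train, s$validation, s$test)) {
        expect_lt(abs(mean(labels[part]) - prev), 2 / length(part) + 1e-9)
      }
    }
  }
})

test_that("degenerate label sets are refused or warned about", {
  expect_error(stratified_split(integer(0)), "empty")
  expect_error(stratified_split(rep(1L, 50)), "both classes")
  expect_warning(stratified_split(c(rep(0L, 50), rep(1L, 3)), seed = 1),
                 "fewer than 5")
})

test_that("class weights follow total/count with equal per-class mass", {
  w <- class_weights(c(rep(1L, 64), rep(0L, 936)))
  expect_equal(unname(w["1"]), 15.625)
  expect_equal(unname(w["0"]), 1000 / 936)
  expect_equal(unname(class_weights(c(rep(0L, 50), rep(1L, 50)))), c(2, 2))
  # weighted class mass identity: weight_i * n_i = total for both classes
  set.seed(2)
  for (i in 1:10) {
    n1 <- sample(5:400, 1); n0 <- sample(5:400, 1)
    labels <- c(rep(1L, n1), rep(0L, n0))
    w <- class_weights(labels)
    expect_equal(unname(w["1"]) * n1, n1 + n0)
    expect_equal(unname(w["0"]) * n0, n1 + n0)
    expect_true(all(w > 0))
    expect_gte(w[["1"]], w[["0"]] * (n0 >= n1))
  }
  expect_error(class_weights(rep(0L, 10)), "both classes")
})

test_that("split manifests serialize the seed, counts, and index lists", {
  labels <- c(rep(1L, 20), rep(0L, 80))
  s <- stratified_split(labels, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(s, path)
  m <- jsonlite::fromJSON(path)
  expect_equal(m$seed, 9L)
  expect_equal(sort(c(m$train, m$validation, m$test)), 1:100)
})
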