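# helper: wrap freshly initialized parameters as a predictable model
raw_model <- function(arch, params) {
  structure(list(arch = arch, params = params), class = "ied_model")
}

test_that("both architectures output per-class probabilities summing to one", {
  set.seed(5)
  x <- array(runif(16 * 20 * 7), c(16, 20, 7))
  for (arch in c("gru", "cnn")) {
    params <- if (arch == "gru") init_gru_params(2) else init_cnn_params(2)
    p <- predict(raw_model(arch, params), x, type = "prob")
    expect_equal(dim(p), c(7L, 2L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, 7), tolerance = 1e-6)
  }
})

test_that("all-zero weights give the indifferent (0.5, 0.5) output", {
  params <- init_gru_params(1)
  params <- lapply(params, function(p) p * 0)
  p <- predict(raw_model("gru", params), array(runif(320 * 3), c(16, 20, 3)),
               type = "prob")
  expect_equal(unname(as.vector(p)), rep(0.5, 6))
})

test_that("predictions are per-sample: permutation-equivariant and batch-size invariant", {
  set.seed(6)
  x <- array(runif(16 * 20 * 23), c(16, 20, 23))
  for (arch in c("gru", "cnn")) {
    params <- if (arch == "gru") init_gru_params(3) else init_cnn_params(3)
    m <- raw_model(arch, params)
    p <- predict(m, x, type = "prob")
    perm <- sample(23)
    expect_equal(predict(m, x[, , perm], type = "prob"), p[perm, ],
                 tolerance = 1e-12)
    expect_equal(predict(m, x, type = "prob", batch_size = 5), p,
                 tolerance = 1e-12)
    # inference is deterministic
    expect_identical(predict(m, x, type = "prob"), p)
  }
})

test_that("the decision rule flags a window iff P(anomaly) >= 0.5", {
  # symmetric zero model sits exactly on the tie: label must be positive
  params <- lapply(init_gru_params(1), function(p) p * 0)
  labs <- predict(raw_model("gru", params), array(0.3, c(16, 20, 4)))
  expect_equal(labs, rep(1L, 4))
})

test_that("malformed window shapes are rejected", {
  fit <- raw_model("gru", init_gru_params(1))
  expect_error(predict(fit, array(0, c(12, 20, 2))), "16 x 20")
  expect_error(fit_ied(array(0, c(16, 10, 4)), labels = c(0, 1, 0, 1)),
               "16 x 20")
})

test_that("both models overfit a small separable window set", {
  d <- separable_windows(n = 1000, prevalence = 0.3, seed = 4)
  split <- stratified_split(d$labels, seed = 1)
  for (arch in c("gru", "cnn")) {
    fit <- fit_ied(d$x, d$labels, arch = arch, split = split,
                   weights = NULL, epochs = if (arch == "gru") 25 else 8,
                   lr = 1e-3, batch_size = 256, seed = 1)
    h <- training_history(fit)
    expect_gte(max(h$train_accuracy), 0.99)
    # and the selected checkpoint generalizes to the held-out windows
    pred <- predict(fit, d$x[, , split$test, drop = FALSE])
    expect_gte(mean(pred == d$labels[split$test]), 0.99)
  }
})

test_that("unit class weights reproduce unweighted training exactly", {
  d <- separable_windows(n = 300, prevalence = 0.25, seed = 9)
  split <- stratified_split(d$labels, seed = 2)
  a <- fit_ied(d$x, d$labels, split = split, weights = NULL, epochs = 3,
               lr = 1e-3, batch_size = 128, seed = 7)
  b <- fit_ied(d$x, d$labels, split = split, weights = c(1, 1), epochs = 3,
               lr = 1e-3, batch_size = 128, seed = 7)
  expect_equal(a$history, b$history, tolerance = 1e-12)
  expect_equal(a$params, b$params, tolerance = 1e-12)
})

test_that("training is reproducible from the seed and selects the earliest best epoch", {
  d <- separable_windows(n = 300, prevalence = 0.25, seed = 11)
  split <- stratified_split(d$labels, seed = 2)
  a <- fit_ied(d$x, d$labels, split = split, epochs = 4, lr = 1e-3,
               batch_size = 128, seed = 5)
  b <- fit_ied(d$x, d$labels, split = split, epochs = 4, lr = 1e-3,
               batch_size = 128, seed = 5)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  # best epoch attains the maximum of the selection series, first time
  series <- a$history$val_balanced_accuracy
  expect_equal(a$best_epoch, which.max(series))
})

test_that("class weighting does not hurt sensitivity on imbalanced data (median over seeds)", {
  # small imbalanced corpora; weighted vs unweighted, BA-selected
  sens <- function(fit, pooled, split) {
    pred <- predict(fit, pooled$x[, , split$test, drop = FALSE])
    evaluate_predictions(pred, pooled$labels[split$test])$sensitivity
  }
  sw <- su <- numeric(3)
  for (s in 1:3) {
    rec <- generate_recording(quick_cfg(duration = 240, seed = 30 + s))
    pooled <- make_windows(derive_banana(rec))
    split <- stratified_split(pooled$labels, seed = s)
    fw <- fit_ied(pooled, split = split, weights = "auto", epochs = 10,
                  lr = 1e-3, batch_size = 256, seed = s)
    fu <- fit_ied(pooled, split = split, weights = NULL, epochs = 10,
                  lr = 1e-3, batch_size = 256, seed = s)
    sw[s] <- sens(fw, pooled, split)
    su[s] <- sens(fu, pooled, split)
  }
  expect_gte(median(sw), median(su))
})
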