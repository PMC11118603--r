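test_that("a 125 Hz recording passes through resampling untouched", {
  rec <- noise_recording(duration = 2, sfreq = 125)
  expect_identical(resample_eeg(rec), rec)
})

test_that("integer-factor decimation halves the sample count and keeps passband amplitude", {
  t250 <- (0:2499) / 250
  sig <- matrix(sin(2 * pi * 10 * t250), 19, 2500, byrow = TRUE,
                dimnames = list(electrodes_1020(), NULL))
  rec <- eeg_recording(sig, 250, recording_id = "sine")
  out <- resample_eeg(rec)
  expect_equal(out$sfreq, 125)
  expect_equal(ncol(out$signal), 1250L)
  # compare against the analytically sampled 125 Hz sine (edges excluded)
  t125 <- (0:1249) / 125
  ref <- sin(2 * pi * 10 * t125)
  mid <- 100:1150
  expect_lt(max(abs(out$signal[1, mid] - ref[mid])), 0.01)
})

test_that("rational resampling handles non-integer ratios", {
  t200 <- (0:1599) / 200
  sig <- matrix(sin(2 * pi * 7 * t200), 19, 1600, byrow = TRUE,
                dimnames = list(electrodes_1020(), NULL))
  out <- resample_eeg(eeg_recording(sig, 200, recording_id = "s"))
  expect_equal(out$sfreq, 125)
  expect_equal(ncol(out$signal), 1000L)
  ref <- sin(2 * pi * 7 * (0:999) / 125)
  mid <- 100:900
  expect_lt(max(abs(out$signal[1, mid] - ref[mid])), 0.02)
})

test_that("rates below 125 Hz are refused", {
  expect_error(resample_eeg(noise_recording(sfreq = 100)), "unsupported")
})

test_that("windowing yields floor(T/20) full windows from timestep zero", {
  sig <- matrix(seq_len(16 * 1250), 16, 1250,
                dimnames = list(paste0("d", 1:16), NULL))
  bip <- eeg_bipolar(sig, 125)
  arr <- window_recording(bip)
  expect_equal(dim(arr), c(16L, 20L, 62L))
  # first window covers timesteps 1..20 in order, channels preserved
  expect_equal(arr[, , 1], sig[, 1:20], ignore_attr = TRUE)
  expect_equal(arr[, , 62], sig[, 1221:1240], ignore_attr = TRUE)
  one <- window_recording(eeg_bipolar(sig[, 1:20], 125))
  expect_equal(dim(one)[3], 1L)
  expect_warning(short <- window_recording(eeg_bipolar(sig[, 1:19], 125)),
                 "shorter")
  expect_equal(dim(short)[3], 0L)
})

test_that("normalization maps row extrema to 0/1, constants to 0.5, and is idempotent", {
  row <- c(-50, 0, 50, seq(-45, 45, length.out = 17))
  m <- matrix(row, 16, 20, byrow = TRUE)
  out <- normalize_window(m)
  expect_equal(out[1, 1], 0)   # row minimum
  expect_equal(out[1, 3], 1)   # row maximum
  expect_equal(out[1, 2], 0.5) # midpoint of the range
  expect_true(all(normalize_window(matrix(7, 16, 20)) == 0.5))
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(rnorm(320, sd = 30), 16, 20)
    n1 <- normalize_window(x)
    expect_true(all(n1 >= 0 & n1 <= 1))
    expect_equal(normalize_window(n1), n1)
    # amplitude invariance: positive rescaling changes nothing
    expect_equal(normalize_window(x * runif(1, 0.1, 10)), n1)
  }
})

test_that("onset labeling follows the half-open 160 ms windows and the k-early shift", {
  ann <- data.frame(onset = 1.0, duration = 0.05, label = "spike")
  lab0 <- label_windows(10, ann, k_early = 0)
  expect_equal(which(lab0 == 1L), 7L)  # window index 6, 0-based
  lab1 <- label_windows(10, ann, k_early = 1)
  expect_equal(which(lab1 == 1L), 6L)  # window index 5
  expect_length(lab1, 9L)              # last window dropped
  expect_equal(sum(label_windows(10, empty_ann())), 0L)
  expect_error(label_windows(10, ann, k_early = -1), "non-negative")
  # only positive-set labels count
  other <- data.frame(onset = 1.0, duration = 0, label = "eye blink")
  expect_equal(sum(label_windows(10, other)), 0L)
  expect_equal(sum(label_windows(10, data.frame(onset = 1, duration = 0,
                                                label = "Sharp Wave"))), 1L)
})

test_that("labels match a brute-force interval scan for random annotation sets", {
  set.seed(42)
  w <- 20 / 125
  for (rep in 1:20) {
    n_win <- sample(30:80, 1)
    k <- sample(0:4, 1)
    onsets <- runif(sample(3:12, 1), 0, n_win * w)
    ann <- data.frame(onset = onsets, duration = 0.05, label = "spike")
    got <- label_windows(n_win, ann, k_early = k)
    want <- integer(n_win - k)
    for (i in seq_along(want)) {
      lo <- w * (i - 1 + k)
      hi <- w * (i + k)
      if (any(onsets >= lo & onsets < hi)) want[i] <- 1L
    }
    expect_identical(got, want)
  }
})

test_that("positives are conserved under the k-early shift up to boundary loss", {
  set.seed(8)
  w <- 20 / 125
  n_win <- 100
  onsets <- runif(25, 0, n_win * w)
  ann <- data.frame(onset = onsets, duration = 0.03, label = "spike")
  base_targets <- floor(onsets / w + 1e-9)
  for (k in c(1L, 3L, 9L)) {
    n_pos_k <- sum(label_windows(n_win, ann, k_early = k))
    expected <- length(unique(base_targets[base_targets - k >= 0])) -
      length(unique(base_targets[base_targets - k >= n_win - k]))
    expect_equal(n_pos_k, expected)
  }
})

test_that("make_windows produces bounded 16 x 20 samples aligned with labels", {
  rec <- generate_recording(quick_cfg(duration = 20, seed = 9))
  w <- make_windows(derive_banana(rec), k_early = 2)
  expect_s3_class(w, "eeg_windows")
  expect_equal(dim(w$x)[1:2], c(16L, 20L))
  expect_equal(dim(w$x)[3], length(w$labels))
  expect_equal(length(w$labels), floor(20 * 125 / 20) - 2L)
  expect_true(all(w$x >= 0 & w$x <= 1))
  expect_equal(w$k_early, 2L)
})

test_that("saved windows reload identically", {
  rec <- generate_recording(quick_cfg(duration = 10, seed = 3))
  w <- make_windows(derive_banana(rec))
  d <- withr::local_tempdir()
  save_windows(w, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_equal(load_windows(d), w)
})
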