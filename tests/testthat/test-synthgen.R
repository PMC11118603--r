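test_that("background has the requested shape, rate, and no annotations", {
  cfg <- quick_cfg(duration = 10)
  rec <- generate_background(cfg)
  expect_equal(dim(rec$signal), c(19L, 2500L))
  expect_equal(rec$sfreq, 250)
  expect_equal(nrow(rec$annotations), 0L)
  expect_true(max(abs(rec$signal)) <= 200)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- quick_cfg(duration = 20)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$annotations, b$annotations)
  c2 <- generate_recording(cfg, seed = cfg$seed + 1L)
  expect_false(identical(a$signal, c2$signal))
})

test_that("a zero event rate yields an event-free recording", {
  rec <- generate_recording(quick_cfg(event_rate = 0, duration = 10))
  expect_equal(nrow(rec$annotations), 0L)
})

test_that("annotated durations obey the spike and sharp-wave ranges", {
  rec <- generate_recording(quick_cfg(duration = 120))
  ann <- rec$annotations
  expect_gt(nrow(ann), 10)
  spikes <- ann$duration[ann$label == "spike"]
  sharps <- ann$duration[ann$label == "sharp wave"]
  expect_true(all(spikes >= 0.020 & spikes <= 0.070))
  expect_true(all(sharps >= 0.070 & sharps <= 0.200))
  # onsets plus durations stay inside the recording
  expect_true(all(ann$onset >= 0))
  expect_true(all(ann$onset + ann$duration <= 120))
})

test_that("every injected event phase-reverses with > 3x background RMS on the two derivations sharing its focus", {
  cfg <- quick_cfg(duration = 120, seed = 11)
  rec <- generate_recording(cfg)
  bip <- derive_banana(rec)
  ev <- attr(rec, "events")
  m <- banana_montage()
  fs <- rec$sfreq
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    d1 <- paste0(m$anterior[m$posterior == e$focus_electrode], "-",
                 e$focus_electrode)
    d2 <- paste0(e$focus_electrode, "-",
                 m$posterior[m$anterior == e$focus_electrode])
    idx <- (floor(e$onset * fs)):(floor((e$onset + e$duration) * fs)) + 1
    # deflection is measured from the local baseline (median over a
    # +-0.5 s context), as EEG amplitudes are read clinically — slow
    # background drift is not part of the transient
    ctx <- max(1, idx[1] - fs %/% 2):min(ncol(bip$signal),
                                         idx[length(idx)] + fs %/% 2)
    a <- bip$signal[d1, idx] - median(bip$signal[d1, ctx])
    b <- bip$signal[d2, idx] - median(bip$signal[d2, ctx])
    pa <- a[which.max(abs(a))]
    pb <- b[which.max(abs(b))]
    expect_true(sign(pa) != sign(pb))
    expect_gt(abs(pa), 3 * sd(bip$signal[d1, ]))
    expect_gt(abs(pb), 3 * sd(bip$signal[d2, ]))
  }
})

test_that("a zero-amplitude injection only appends the annotation at the apex time", {
  rec <- generate_background(quick_cfg(duration = 5))
  ev <- ground_truth_event(2, 0.05, "spike", "T3")
  out <- inject_event(rec, ev, amplitude = 0)
  expect_equal(out$signal, rec$signal)
  expect_equal(nrow(out$annotations), 1L)
  expect_equal(out$annotations$onset, 2 + 0.18 * 0.05)
})

test_that("injection validates focus electrode and bounds, and warns on overlap", {
  rec <- generate_background(quick_cfg(duration = 5))
  expect_error(inject_event(rec, ground_truth_event(1, 0.05, "spike", "Fp1"), 100),
               "interior")
  expect_error(inject_event(rec, ground_truth_event(4.99, 0.05, "spike", "T3"), 100),
               "fit inside")
  once <- inject_event(rec, ground_truth_event(2, 0.1, "sharp_wave", "C3"), 100)
  expect_warning(inject_event(once, ground_truth_event(2.05, 0.1, "spike", "C3"), 100),
                 "overlap")
})

test_that("positive-window prevalence is near the configured 8% target", {
  cfg <- quick_cfg(duration = 1800, seed = 21)
  rec <- generate_recording(cfg)
  labels <- label_windows(floor(1800 * 125 / 20), rec$annotations)
  expect_lt(abs(mean(labels) - 0.08), 0.02)
})

test_that("generate_eeg_dataset writes EDFs plus a reproducible ground-truth table", {
  td <- withr::local_tempdir()
  cfg <- quick_cfg(n_recordings = 2, duration = 10, seed = 5)
  res <- generate_eeg_dataset(cfg, file.path(td, "a"))
  expect_length(res$paths, 2L)
  expect_true(all(file.exists(res$paths)))
  expect_true(file.exists(res$ground_truth_path))
  res2 <- generate_eeg_dataset(cfg, file.path(td, "b"))
  expect_identical(readLines(res$ground_truth_path),
                   readLines(res2$ground_truth_path))
  # round trip: EDF annotations match ground truth within one sample
  rec <- read_edf(res$paths[1])
  gt <- res$ground_truth[res$ground_truth$recording_id == "rec01", ]
  expect_equal(sort(rec$annotations$onset), sort(gt$onset_s),
               tolerance = 1 / cfg$sampling_rate)
})
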