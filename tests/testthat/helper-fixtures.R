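# Shared fixtures, built in code.

# referential recording with every electrode at a constant (or supplied
# per-channel) value
const_recording <- function(value = 0, duration = 1, sfreq = 250,
                            id = "const") {
  n <- as.integer(duration * sfreq)
  sig <- matrix(value, length(electrodes_1020()), n,
                dimnames = list(electrodes_1020(), NULL))
  eeg_recording(sig, sfreq, recording_id = id)
}

# random-noise referential recording (seeded)
noise_recording <- function(duration = 2, sfreq = 250, seed = 99,
                            id = "noise") {
  set.seed(seed)
  n <- as.integer(duration * sfreq)
  sig <- matrix(rnorm(19 * n, sd = 10), 19, n,
                dimnames = list(electrodes_1020(), NULL))
  eeg_recording(sig, sfreq, recording_id = id)
}

# small synthetic configuration for quick tests
quick_cfg <- function(...) {
  args <- modifyList(list(n_recordings = 1, duration = 30, seed = 7),
                     list(...))
  do.call(synth_config, args)
}

# a tiny trivially separable window set: positives high-valued, negatives
# low-valued, with a whiff of noise so batch-norm variances are non-zero
separable_windows <- function(n = 200, prevalence = 0.5, seed = 3) {
  set.seed(seed)
  labels <- as.integer(runif(n) < prevalence)
  x <- array(0, c(16, 20, n))
  for (i in seq_len(n)) {
    base <- if (labels[i] == 1L) 0.9 else 0.1
    x[, , i] <- base + matrix(rnorm(320, sd = 0.02), 16, 20)
  }
  list(x = pmin(pmax(x, 0), 1), labels = labels)
}

empty_ann <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}
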