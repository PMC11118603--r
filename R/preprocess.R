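# Resampling, windowing, normalization, labeling.

# Zero-phase rational resampler: zero-stuff by p, low-pass below the
# tighter of the two Nyquist limits with a forward-backward (zero-phase)
# FIR, then take every q-th sample. For integer decimation p = 1 and this
# reduces to FIR low-pass + sub-selection.
rational_resample <- function(x, p, q, fs_in) {
  if (p == 1 && q == 1) return(x)
  n <- length(x)
  up <- if (p > 1) {
    u <- numeric(n * p)
    u[seq(1, length(u), by = p)] <- x * p   # gain p restores amplitude
    u
  } else x
  fs_up <- fs_in * p
  cutoff <- 0.9 * min(fs_up / (2 * p), fs_up / (2 * q))
  ntaps <- max(30, 10 * max(p, q))
  if (ntaps %% 2 == 1) ntaps <- ntaps + 1
  h <- as.numeric(signal::fir1(ntaps, cutoff / (fs_up / 2)))
  filtered <- signal::filtfilt(h, 1, up)
  filtered[seq(1, length(filtered), by = q)]
}

#' Resample a recording to 125 Hz
#'
#' Applies a zero-phase low-pass FIR (cutoff below the new Nyquist of
#' 62.5 Hz) followed by sample sub-selection; non-integer rate ratios are
#' handled by rational (zero-stuff / filter / sub-select) resampling.
#' Annotation times are in seconds and therefore unchanged. A recording
#' already at 125 Hz is returned untouched.
#'
#' @param recording an [eeg_recording()] or [eeg_bipolar()].
#' @param target target rate in Hz (125 for the classifier).
#' @return the recording at `target` Hz.
#' @export
resample_eeg <- function(recording, target = TARGET_RATE) {
  fs <- recording$sfreq
  if (fs == target) return(recording)
  if (fs < target)
    stop("unsupported rate: source ", fs, " Hz is below the ", target,
         " Hz target (upsampling is not part of this pipeline)")
  ratio <- frac_reduce(target, fs)
  sig <- t(apply(recording$signal, 1, rational_resample,
                 p = ratio[1], q = ratio[2], fs_in = fs))
  rownames(sig) <- rownames(recording$signal)
  recording$signal <- sig
  recording$sfreq <- target
  recording
}

frac_reduce <- function(num, den) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  num <- round(num * 1e6); den <- round(den * 1e6)
  d <- g(num, den)
  c(num / d, den / d)
}

#' Cut a bipolar recording into non-overlapping 20-timestep windows
#'
#' Windows start at timestep 0 and are consecutive; window `i` (0-based)
#' covers timesteps `[20*i, 20*(i+1))` of the 125 Hz signal, i.e. seconds
#' `[0.16*i, 0.16*(i+1))`. A trailing partial window is dropped.
#'
#' @param bipolar an [eeg_bipolar()] at 125 Hz.
#' @return numeric array of dimension `c(16, 20, n_windows)` of raw
#'   (unnormalized) window matrices.
#' @export
window_recording <- function(bipolar) {
  stopifnot(inherits(bipolar, "eeg_bipolar"))
  if (bipolar$sfreq != TARGET_RATE)
    stop("windowing requires a ", TARGET_RATE, " Hz recording; call resample_eeg() first")
  n_ch <- nrow(bipolar$signal)
  n_t <- ncol(bipolar$signal)
  n_win <- floor(n_t / WINDOW_STEPS)
  if (n_win == 0) {
    warning("recording shorter than one window; returning no windows")
    return(array(0, dim = c(n_ch, WINDOW_STEPS, 0)))
  }
  used <- bipolar$signal[, seq_len(n_win * WINDOW_STEPS), drop = FALSE]
  arr <- array(used, dim = c(n_ch, WINDOW_STEPS, n_win))
  # array() fills column-major over (channel, time): dim 1 iterates
  # channels fastest, matching the channels x timepoints layout
  dimnames(arr) <- list(rownames(bipolar$signal), NULL, NULL)
  arr
}

#' Min-max normalize a window per channel
#'
#' Each row (channel) of the 16 x 20 window is linearly rescaled so its
#' minimum maps to 0 and maximum to 1, using that row's extrema within the
#' window. A constant row — where the map is undefined — is set to the
#' neutral mid-scale 0.5.
#'
#' @param raw numeric matrix (channels x timesteps).
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_window <- function(raw) {
  lo <- apply(raw, 1, min)
  hi <- apply(raw, 1, max)
  rng <- hi - lo
  flat <- rng <= 0
  rng[flat] <- 1
  out <- (raw - lo) / rng
  out[flat, ] <- 0.5
  out
}

# Vectorized normalization of a (ch x steps x n) window array.
normalize_windows <- function(arr) {
  d <- dim(arr)
  if (d[3] == 0) return(arr)
  for (i in seq_len(d[3])) arr[, , i] <- normalize_window(arr[, , i])
  arr
}

#' Label windows from annotation onsets, optionally k windows early
#'
#' Window `i` (0-based) receives label 1 iff some positive annotation
#' onset `t` falls in `[0.16*(i + k_early), 0.16*(i + k_early + 1))` —
#' i.e. with `k_early > 0` a window is positive when the event starts
#' `k_early` windows later, training a detector that fires ahead of the
#' discharge. The last `k_early` windows have no lookahead target and are
#' dropped, so the returned vector has `n_windows - k_early` entries.
#'
#' Only the onset is used, matching the annotation semantics of a marked
#' time point; an alternative any-overlap rule (an event labels every
#' window its duration touches) is available via `rule = "overlap"`.
#'
#' @param n_windows number of windows cut from the recording.
#' @param annotations annotation data frame (`onset`, `duration`, `label`).
#' @param k_early integer in `[0, 9]`: how many windows ahead to look.
#' @param positive_labels labels counted as anomalies (case-insensitive).
#' @param rule `"onset"` (default) or `"overlap"`.
#' @return integer vector of 0/1 labels, length `n_windows - k_early`.
#' @export
label_windows <- function(n_windows, annotations, k_early = 0,
                          positive_labels = DEFAULT_POSITIVE_LABELS,
                          rule = c("onset", "overlap")) {
  rule <- match.arg(rule)
  if (k_early < 0) stop("k_early must be non-negative")
  if (k_early > 9) stop("k_early beyond 9 windows is not supported")
  n_keep <- max(n_windows - k_early, 0L)
  labels <- integer(n_keep)
  if (n_keep == 0) return(labels)
  pos <- annotations[tolower(trimws(annotations$label)) %in%
                       tolower(positive_labels), , drop = FALSE]
  if (!nrow(pos)) return(labels)
  w <- WINDOW_SECONDS
  if (rule == "onset") {
    target <- floor(pos$onset / w + 1e-9) - k_early
    target <- target[target >= 0 & target < n_keep]
    labels[target + 1L] <- 1L
  } else {
    for (i in seq_len(nrow(pos))) {
      first <- floor(pos$onset[i] / w + 1e-9) - k_early
      last <- floor((pos$onset[i] + pos$duration[i]) / w - 1e-9) - k_early
      span <- max(first, 0):min(last, n_keep - 1L)
      if (length(span) && span[1] <= span[length(span)])
        labels[span + 1L] <- 1L
    }
  }
  labels
}

#' Build labeled, normalized window samples from a bipolar recording
#'
#' Convenience wrapper: checks/establishes the 125 Hz rate, cuts windows,
#' normalizes each, and labels them with the k-early scheme. The window
#' array is truncated to the labeled length (the last `k_early` windows
#' carry no label and are dropped).
#'
#' @param bipolar an [eeg_bipolar()]; resampled to 125 Hz if needed.
#' @param k_early lookahead in windows, see [label_windows()].
#' @param positive_labels forwarded to [label_windows()].
#' @param rule forwarded to [label_windows()].
#' @return object of class `eeg_windows`: list with `x` (16 x 20 x n
#'   array in `[0, 1]`), `labels` (0/1 integer vector), `window_index`
#'   (0-based), `recording_id`, `k_early`, `prevalence`.
#' @export
make_windows <- function(bipolar, k_early = 0,
                         positive_labels = DEFAULT_POSITIVE_LABELS,
                         rule = c("onset", "overlap")) {
  bipolar <- resample_eeg(bipolar)
  raw <- window_recording(bipolar)
  labels <- label_windows(dim(raw)[3], bipolar$annotations, k_early,
                          positive_labels, rule)
  n <- length(labels)
  x <- normalize_windows(raw[, , seq_len(n), drop = FALSE])
  structure(list(x = x, labels = labels,
                 window_index = seq_len(n) - 1L,
                 recording_id = rep(bipolar$recording_id, n),
                 k_early = as.integer(k_early),
                 prevalence = if (n) mean(labels) else NA_real_),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %d windows (16 x 20), %.2f%% positive, k_early = %d\n",
              length(x$labels), 100 * x$prevalence, x$k_early))
  invisible(x)
}

#' Pool window sets from several recordings
#'
#' @param window_list list of `eeg_windows` objects with a common
#'   `k_early`.
#' @return a single pooled `eeg_windows` object.
#' @export
bind_windows <- function(window_list) {
  stopifnot(length(window_list) >= 1,
            all(vapply(window_list, inherits, TRUE, "eeg_windows")))
  ks <- vapply(window_list, `[[`, 0L, "k_early")
  if (length(unique(ks)) != 1) stop("window sets have differing k_early")
  xs <- lapply(window_list, `[[`, "x")
  n_tot <- sum(vapply(xs, function(a) dim(a)[3], 0))
  x <- array(0, dim = c(dim(xs[[1]])[1], dim(xs[[1]])[2], n_tot))
  at <- 0
  for (a in xs) {
    if (dim(a)[3]) x[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  labels <- unlist(lapply(window_list, `[[`, "labels"), use.names = FALSE)
  structure(list(x = x, labels = as.integer(labels),
                 window_index = unlist(lapply(window_list, `[[`, "window_index"),
                                       use.names = FALSE),
                 recording_id = unlist(lapply(window_list, `[[`, "recording_id"),
                                       use.names = FALSE),
                 k_early = ks[1],
                 prevalence = mean(labels)),
            class = "eeg_windows")
}

#' Preprocess a directory of EDF files into pooled labeled windows
#'
#' Reads every `.edf` file under `in_dir`, derives the banana montage,
#' resamples to 125 Hz, and pools the labeled windows of all recordings.
#'
#' @param in_dir directory containing EDF(+) files.
#' @param k_early forwarded to [make_windows()].
#' @param positive_labels forwarded to [label_windows()].
#' @return a pooled `eeg_windows` object.
#' @export
preprocess_dir <- function(in_dir, k_early = 0,
                           positive_labels = DEFAULT_POSITIVE_LABELS) {
  paths <- sort(list.files(in_dir, pattern = "\\.edf$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(paths)) stop("no EDF files found in ", in_dir)
  sets <- lapply(paths, function(p) {
    make_windows(derive_banana(read_edf(p)), k_early = k_early,
                 positive_labels = positive_labels)
  })
  bind_windows(sets)
}

#' Save / load labeled windows
#'
#' Windows are stored as an RDS array next to a JSON manifest recording
#' the provenance (recording ids, `k_early`, window count, prevalence).
#'
#' @param windows an `eeg_windows` object.
#' @param dir output directory (created if needed).
#' @return `save_windows()` returns `dir` invisibly; `load_windows()`
#'   returns the `eeg_windows` object.
#' @export
save_windows <- function(windows, dir) {
  stopifnot(inherits(windows, "eeg_windows"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(windows, file.path(dir, "windows.rds"))
  manifest <- list(recording_ids = unique(windows$recording_id),
                   k_early = windows$k_early,
                   window_count = length(windows$labels),
                   prevalence = windows$prevalence)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_windows
#' @export
load_windows <- function(dir) {
  readRDS(file.path(dir, "windows.rds"))
}
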