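#' Configuration for the synthetic ICU-EEG generator
#'
#' Bundles every parameter of the annotated-EEG simulator. Defaults emulate
#' the recording conditions the detector is built for: 19-electrode
#' referential scalp EEG at 250 Hz (so that downsampling to 125 Hz is
#' exercised), ongoing background activity, and rare epileptiform
#' transients — spikes of 20-70 ms and sharp waves of 70-200 ms — at a rate
#' chosen so that roughly 8% of 160 ms windows contain an event onset.
#'
#' @param n_recordings number of recordings to simulate.
#' @param duration seconds per recording (whole seconds).
#' @param sampling_rate Hz, must be >= 125.
#' @param event_rate events per minute. The default 31/min gives an
#'   expected onset-per-window probability of about 8%.
#' @param spike_fraction fraction of events that are spikes (the rest are
#'   sharp waves).
#' @param spike_duration_range,sharp_duration_range event duration bounds
#'   in seconds.
#' @param event_amplitude_range peak amplitude bounds at the focus
#'   electrode, microvolts.
#' @param background_amplitude RMS of the ongoing background activity per
#'   electrode, microvolts.
#' @param seed integer seed; the full dataset is a deterministic function
#'   of the configuration including this seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_recordings = 3,
                         duration = 900,
                         sampling_rate = 250,
                         event_rate = 31,
                         spike_fraction = 0.5,
                         spike_duration_range = c(0.020, 0.070),
                         sharp_duration_range = c(0.070, 0.200),
                         event_amplitude_range = c(120, 180),
                         background_amplitude = 6,
                         seed = 1) {
  cfg <- list(n_recordings = as.integer(n_recordings),
              duration = duration,
              sampling_rate = sampling_rate,
              event_rate = event_rate,
              spike_fraction = spike_fraction,
              spike_duration_range = spike_duration_range,
              sharp_duration_range = sharp_duration_range,
              event_amplitude_range = event_amplitude_range,
              background_amplitude = background_amplitude,
              seed = as.integer(seed))
  if (cfg$n_recordings < 1) stop("n_recordings must be >= 1")
  if (!is.numeric(duration) || duration <= 0 || duration != round(duration))
    stop("duration must be a positive whole number of seconds")
  if (sampling_rate < 125)
    stop("sampling_rate must be >= 125 Hz (the pipeline downsamples, never upsamples)")
  if (sampling_rate != round(sampling_rate))
    stop("sampling_rate must be an integer number of Hz")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must be in [0, 1]")
  ok_range <- function(r) length(r) == 2 && all(r > 0) && r[1] <= r[2]
  if (!ok_range(cfg$spike_duration_range) || !ok_range(cfg$sharp_duration_range))
    stop("duration ranges must be positive and ordered")
  if (cfg$spike_duration_range[2] > cfg$sharp_duration_range[1] + 1e-12)
    stop("spike durations must not exceed the shortest sharp-wave duration")
  if (!ok_range(cfg$event_amplitude_range))
    stop("event_amplitude_range must be positive and ordered")
  if (background_amplitude <= 0) stop("background_amplitude must be > 0")
  if (event_rate < 0) stop("event_rate must be >= 0")
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d recording(s) x %g s @ %g Hz, ",
                     "%g events/min (%.0f%% spikes), seed %d\n"),
              x$n_recordings, x$duration, x$sampling_rate, x$event_rate,
              100 * x$spike_fraction, x$seed))
  invisible(x)
}

#' A ground-truth epileptiform event
#'
#' @param onset seconds from recording start.
#' @param duration seconds.
#' @param event_type `"spike"` or `"sharp_wave"`.
#' @param focus_electrode 10-20 electrode name; must be interior to a
#'   montage chain so that two bipolar derivations share it.
#' @return object of class `gt_event`.
#' @export
ground_truth_event <- function(onset, duration, event_type, focus_electrode) {
  event_type <- match.arg(event_type, c("spike", "sharp_wave"))
  if (onset < 0) stop("event onset must be >= 0")
  if (duration <= 0) stop("event duration must be > 0")
  structure(list(onset = onset, duration = duration, event_type = event_type,
                 focus_electrode = focus_electrode),
            class = "gt_event")
}

# Smooth biphasic transient on [0, 1] built as a difference of two raised
# cosines: a steep rise to a dominant apex early in the event (epileptiform
# discharges are apiculate, with a fast upstroke) followed by a smaller,
# slower opposite rebound — the after-going slow wave — returning to
# baseline. The dominant lobe makes the sign of the maximum deflection
# unambiguous, as in clinical discharges. Peak normalized to 1.
raised_cos <- function(u, center, width) {
  ifelse(abs(u - center) <= width / 2,
         0.5 * (1 + cos(2 * pi * (u - center) / width)), 0)
}

# apex position as a fraction of the event duration; the annotation marks
# this time, the way a clinician marks a discharge at its most prominent
# point
TEMPLATE_APEX <- 0.18

event_template_raw <- function(u) {
  raised_cos(u, TEMPLATE_APEX, 2 * TEMPLATE_APEX) -
    0.4 * raised_cos(u, 0.55, 0.7)
}

template_peak <- local({
  u <- seq(0, 1, length.out = 4001)
  max(abs(event_template_raw(u)))
})

event_template <- function(u) event_template_raw(u) / template_peak

#' Generate ongoing background EEG
#'
#' Produces a 19-electrode referential recording of stationary 1/f-shaped
#' ("pink") noise plus a low-amplitude 8-12 Hz posterior-dominant rhythm,
#' with an empty annotation list. Against this background the injected
#' transients are morphologically salient, the way clinicians expect to
#' spot discharges at a glance.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param recording_id identifier for the returned recording.
#' @return an [eeg_recording()] with 19 rows and
#'   `duration * sampling_rate` columns.
#' @export
generate_background <- function(config, seed = config$seed,
                                recording_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  electrodes <- electrodes_1020()

  # per-electrode colored noise, independent across electrodes; amplitude
  # falls as 1/f (power ~ 1/f^2, the scaling of scalp EEG), flat below
  # 1 Hz, so the trace is smooth at 125 Hz the way clinical EEG is
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)          # two-sided frequency axis
  shape <- 1 / pmax(freqs, 1)
  shape[1] <- 0                             # no DC drift
  sig <- matrix(0, length(electrodes), n, dimnames = list(electrodes, NULL))
  for (e in seq_along(electrodes)) {
    spec <- stats::fft(stats::rnorm(n)) * shape
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    sig[e, ] <- x / stats::sd(x) * config$background_amplitude
  }

  # shared posterior-dominant alpha rhythm with slow amplitude modulation;
  # per-electrode gain jitter keeps it from cancelling exactly in bipolar
  # derivations
  t <- (seq_len(n) - 1) / fs
  f_alpha <- stats::runif(1, 8, 12)
  envelope <- 1 + 0.5 * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
  alpha <- sin(2 * pi * f_alpha * t + stats::runif(1, 0, 2 * pi)) * envelope
  topo <- c(Fp1 = 0.3, Fp2 = 0.3, F3 = 0.4, F4 = 0.4, F7 = 0.4, F8 = 0.4,
            Fz = 0.4, C3 = 0.6, C4 = 0.6, Cz = 0.6, P3 = 1, P4 = 1, Pz = 1,
            T3 = 0.6, T4 = 0.6, T5 = 1, T6 = 1, O1 = 1, O2 = 1)
  gain <- stats::runif(length(electrodes), 0.8, 1.2)
  amp <- 0.5 * config$background_amplitude * topo[electrodes] * gain
  sig <- sig + outer(unname(amp), alpha)

  eeg_recording(sig, fs, empty_annotations(), recording_id)
}

#' Inject an epileptiform transient into a recording
#'
#' Adds a smooth biphasic pulse of the event's duration at the focus
#' electrode (full amplitude) and its chain neighbours (half amplitude),
#' and appends the event to the annotation table, marked at its apex time
#' (the time point a clinician would mark). After bipolar derivation
#' the two channels sharing the focus electrode carry opposite-sign peak
#' deflections — the "tip to tip" phase reversal used to localize
#' discharges.
#'
#' @param recording an [eeg_recording()].
#' @param event a [ground_truth_event()].
#' @param amplitude peak deflection at the focus electrode, microvolts.
#' @return the recording with the event added.
#' @export
inject_event <- function(recording, event, amplitude) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(event, "gt_event"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  interior <- interior_electrodes()
  if (!event$focus_electrode %in% interior)
    stop("focus electrode '", event$focus_electrode,
         "' is not interior to a montage chain")
  dur_rec <- recording_duration(recording)
  if (event$onset + event$duration > dur_rec + 1e-9)
    stop("event does not fit inside the recording")

  ann <- recording$annotations
  if (nrow(ann)) {
    overlap <- ann$onset < event$onset + event$duration &
      ann$onset + ann$duration > event$onset
    if (any(overlap))
      warning("injected event overlaps an existing event")
  }

  fs <- recording$sfreq
  i0 <- floor(event$onset * fs) + 1
  i1 <- min(floor((event$onset + event$duration) * fs) + 1, ncol(recording$signal))
  idx <- i0:i1
  u <- ((idx - 1) / fs - event$onset) / event$duration
  u <- pmin(pmax(u, 0), 1)
  pulse <- event_template(u)
  # rescale the sampled pulse so `amplitude` is the realized peak even for
  # spikes only a few samples long at the native rate
  pk <- max(abs(pulse))
  pulse <- if (pk > 0) amplitude * pulse / pk else amplitude * pulse
  recording$signal[event$focus_electrode, idx] <-
    recording$signal[event$focus_electrode, idx] + pulse
  for (nb in chain_neighbours(event$focus_electrode)) {
    recording$signal[nb, idx] <- recording$signal[nb, idx] + 0.5 * pulse
  }

  label <- if (event$event_type == "spike") "spike" else "sharp wave"
  # the annotation marks the apex — the time point a clinician clicks on —
  # not the latent physical start of the transient
  recording$annotations <- rbind(
    ann, data.frame(onset = event$onset + TEMPLATE_APEX * event$duration,
                    duration = event$duration,
                    label = label, stringsAsFactors = FALSE))
  recording
}

# Draw the event schedule for one recording: onsets follow a renewal
# process (exponential gaps plus the previous event's duration as dead
# time) whose rate is corrected so the realized onset rate matches
# `event_rate`; types, durations, amplitudes and foci are drawn i.i.d.
draw_events <- function(config) {
  if (config$event_rate <= 0) return(NULL)
  rate_s <- config$event_rate / 60
  mean_dur <- config$spike_fraction * mean(config$spike_duration_range) +
    (1 - config$spike_fraction) * mean(config$sharp_duration_range)
  gap_mean <- max(1 / rate_s - mean_dur, 0.05)
  interior <- interior_electrodes()
  max_dur <- config$sharp_duration_range[2]

  t_cursor <- stats::rexp(1, 1 / gap_mean)
  events <- list()
  while (t_cursor + 1.2 * max_dur < config$duration) {
    is_spike <- stats::runif(1) < config$spike_fraction
    rng <- if (is_spike) config$spike_duration_range else config$sharp_duration_range
    dur <- stats::runif(1, rng[1], rng[2])
    events[[length(events) + 1L]] <- list(
      onset = t_cursor, duration = dur,
      event_type = if (is_spike) "spike" else "sharp_wave",
      focus_electrode = sample(interior, 1),
      amplitude = stats::runif(1, config$event_amplitude_range[1],
                               config$event_amplitude_range[2]))
    t_cursor <- t_cursor + dur + stats::rexp(1, 1 / gap_mean)
  }
  events
}

#' Generate one annotated synthetic recording
#'
#' Background activity plus a seeded schedule of spike / sharp-wave events.
#'
#' @inheritParams generate_background
#' @return an [eeg_recording()] whose annotation table holds every injected
#'   event.
#' @export
generate_recording <- function(config, seed = config$seed,
                               recording_id = "synthetic") {
  rec <- generate_background(config, seed = seed, recording_id = recording_id)
  # RNG stream continues past the background draw, so the schedule is a
  # deterministic function of (config, seed) as well
  events <- draw_events(config)
  # inject in place on a local matrix: one signal copy for the whole
  # schedule instead of one per event
  sig <- rec$signal
  rec$signal <- NULL
  fs <- config$sampling_rate
  n_t <- ncol(sig)
  for (ev in events) {
    i0 <- floor(ev$onset * fs) + 1
    i1 <- min(floor((ev$onset + ev$duration) * fs) + 1, n_t)
    idx <- i0:i1
    u <- pmin(pmax(((idx - 1) / fs - ev$onset) / ev$duration, 0), 1)
    pulse <- event_template(u)
    pk <- max(abs(pulse))
    if (pk > 0) pulse <- pulse / pk
    pulse <- ev$amplitude * pulse
    sig[ev$focus_electrode, idx] <- sig[ev$focus_electrode, idx] + pulse
    for (nb in chain_neighbours(ev$focus_electrode))
      sig[nb, idx] <- sig[nb, idx] + 0.5 * pulse
  }
  ann <- if (length(events)) {
    data.frame(
      onset = vapply(events, `[[`, 0, "onset") +
        TEMPLATE_APEX * vapply(events, `[[`, 0, "duration"),
      duration = vapply(events, `[[`, 0, "duration"),
      label = ifelse(vapply(events, `[[`, "", "event_type") == "spike",
                     "spike", "sharp wave"),
      stringsAsFactors = FALSE)
  } else {
    empty_annotations()
  }
  rec <- eeg_recording(sig, fs, ann, recording_id)
  attr(rec, "events") <- if (length(events)) {
    data.frame(onset = vapply(events, `[[`, 0, "onset"),
               duration = vapply(events, `[[`, 0, "duration"),
               type = vapply(events, `[[`, "", "event_type"),
               focus_electrode = vapply(events, `[[`, "", "focus_electrode"),
               amplitude = vapply(events, `[[`, 0, "amplitude"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(onset = numeric(0), duration = numeric(0),
               type = character(0), focus_electrode = character(0),
               amplitude = numeric(0), stringsAsFactors = FALSE)
  }
  rec
}

#' Generate and persist a synthetic annotated-EEG dataset
#'
#' Writes `n_recordings` EDF(+) files with embedded annotations plus a
#' sidecar ground-truth CSV (`ground_truth.csv` with columns
#' `recording_id`, `onset_s`, `duration_s`, `type`, `focus_electrode`).
#' Fully reproducible from the configuration seed.
#'
#' @param config a [synth_config()].
#' @param out_dir writable output directory (created if absent).
#' @return invisibly, a list with `paths` (EDF file paths),
#'   `ground_truth_path`, and the `ground_truth` data frame.
#' @export
generate_eeg_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  paths <- character(config$n_recordings)
  gt <- vector("list", config$n_recordings)
  for (i in seq_len(config$n_recordings)) {
    rid <- sprintf("rec%02d", i)
    rec <- generate_recording(config, seed = config$seed + 7919L * i,
                              recording_id = rid)
    path <- file.path(out_dir, paste0(rid, ".edf"))
    write_edf(rec, path)
    paths[i] <- path
    ev <- attr(rec, "events")
    gt[[i]] <- data.frame(
      recording_id = rep(rid, nrow(ev)),
      onset_s = ev$onset + TEMPLATE_APEX * ev$duration,  # annotated apex
      duration_s = ev$duration, type = ev$type,
      focus_electrode = ev$focus_electrode, stringsAsFactors = FALSE)
  }
  gt_df <- do.call(rbind, gt)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  write.csv(gt_df, gt_path, row.names = FALSE)
  invisible(list(paths = paths, ground_truth_path = gt_path,
                 ground_truth = gt_df))
}
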