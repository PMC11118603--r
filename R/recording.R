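#' EEG recording containers
#'
#' `eeg_recording()` wraps a referential (common-reference) multichannel EEG
#' signal; `eeg_bipolar()` wraps a bipolar-derived signal. Both hold the
#' signal as a channels-by-timepoints matrix in microvolts, a single
#' sampling rate, and an annotation table with columns `onset` (seconds from
#' recording start), `duration` (seconds) and `label`.
#'
#' @param signal numeric matrix, channels x timepoints, microvolts. Row
#'   names are the channel (or derivation) labels.
#' @param sfreq sampling rate in Hz.
#' @param annotations data frame with columns `onset`, `duration`, `label`;
#'   may have zero rows.
#' @param recording_id character scalar identifying the recording.
#' @return An object of class `eeg_recording` or `eeg_bipolar`.
#' @export
eeg_recording <- function(signal, sfreq, annotations = empty_annotations(),
                          recording_id = "rec") {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)))
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("`sfreq` must be a single positive number")
  annotations <- validate_annotations(annotations, ncol(signal) / sfreq)
  structure(
    list(channels = rownames(signal), sfreq = sfreq, signal = signal,
         annotations = annotations, recording_id = recording_id),
    class = "eeg_recording")
}

#' @rdname eeg_recording
#' @export
eeg_bipolar <- function(signal, sfreq, annotations = empty_annotations(),
                        recording_id = "rec") {
  out <- eeg_recording(signal, sfreq, annotations, recording_id)
  names(out)[names(out) == "channels"] <- "derivations"
  out$derivations <- rownames(signal)
  out["channels"] <- NULL
  structure(out[c("derivations", "sfreq", "signal", "annotations",
                  "recording_id")],
            class = "eeg_bipolar")
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

validate_annotations <- function(annotations, rec_duration) {
  stopifnot(is.data.frame(annotations),
            all(c("onset", "duration", "label") %in% names(annotations)))
  annotations <- annotations[, c("onset", "duration", "label")]
  if (nrow(annotations)) {
    if (any(annotations$onset < 0))
      stop("annotation onsets must be non-negative")
    if (any(annotations$onset > rec_duration + 1e-9))
      stop("annotation onset beyond end of recording")
  }
  annotations
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s'>  %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$recording_id, nrow(x$signal), ncol(x$signal), x$sfreq,
              ncol(x$signal) / x$sfreq, nrow(x$annotations)))
  invisible(x)
}

#' @export
print.eeg_bipolar <- function(x, ...) {
  cat(sprintf("<eeg_bipolar '%s'>  %d derivations x %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$recording_id, nrow(x$signal), ncol(x$signal), x$sfreq,
              ncol(x$signal) / x$sfreq, nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x an `eeg_recording` or `eeg_bipolar`.
#' @return numeric scalar, seconds.
#' @export
recording_duration <- function(x) ncol(x$signal) / x$sfreq
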