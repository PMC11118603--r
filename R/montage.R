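#' The longitudinal bipolar ("double banana") montage
#'
#' Returns the fixed 16-pair montage used throughout the package: the left
#' and right temporal chains followed by the left and right parasagittal
#' chains. Each derivation is anterior electrode minus posterior electrode.
#' The midline chain (Fz-Cz, Cz-Pz) is deliberately excluded: the
#' classifier input is 16 channels.
#'
#' @return data frame with columns `anterior`, `posterior` and 16 rows, in
#'   the canonical channel order.
#' @export
banana_montage <- function() {
  chains <- list(
    c("Fp1", "F7", "T3", "T5", "O1"),   # left temporal
    c("Fp2", "F8", "T4", "T6", "O2"),   # right temporal
    c("Fp1", "F3", "C3", "P3", "O1"),   # left parasagittal
    c("Fp2", "F4", "C4", "P4", "O2"))   # right parasagittal
  pairs <- do.call(rbind, lapply(chains, function(ch)
    data.frame(anterior = ch[-length(ch)], posterior = ch[-1],
               stringsAsFactors = FALSE)))
  pairs
}

#' The 19 scalp electrodes of the 10-20 system used here
#' @return character vector of electrode names (old temporal nomenclature).
#' @export
electrodes_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
    "P3", "P4", "Pz", "T3", "T4", "T5", "T6", "O1", "O2")
}

# Electrodes that appear as both anterior and posterior member of a chain;
# a discharge focused here produces a phase reversal on the two derivations
# sharing it.
interior_electrodes <- function(montage = banana_montage()) {
  intersect(unique(montage$anterior), unique(montage$posterior))
}

# Chain neighbours of an interior electrode (the electrodes it is paired
# with in its chain).
chain_neighbours <- function(electrode, montage = banana_montage()) {
  unique(c(montage$posterior[montage$anterior == electrode],
           montage$anterior[montage$posterior == electrode]))
}

#' Derive the bipolar banana montage from a referential recording
#'
#' Each output row k is `signal[anterior_k, ] - signal[posterior_k, ]`,
#' elementwise, so any common-mode component (shared reference activity)
#' cancels. Annotations are carried over unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param montage data frame of electrode pairs; defaults to
#'   [banana_montage()].
#' @return an [eeg_bipolar()] with one row per pair, named `"A-B"`.
#' @export
derive_banana <- function(recording, montage = banana_montage()) {
  stopifnot(inherits(recording, "eeg_recording"))
  needed <- unique(c(montage$anterior, montage$posterior))
  missing <- setdiff(needed, recording$channels)
  if (length(missing))
    stop("recording lacks montage electrode(s): ",
         paste(missing, collapse = ", "))
  sig <- recording$signal[montage$anterior, , drop = FALSE] -
    recording$signal[montage$posterior, , drop = FALSE]
  rownames(sig) <- paste0(montage$anterior, "-", montage$posterior)
  eeg_bipolar(sig, recording$sfreq, recording$annotations,
              recording$recording_id)
}
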