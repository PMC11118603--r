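# EDF(+) reading and writing.
#
# EDF stores a 256-byte global header, one 256-byte header block per
# signal (field-major), then data records of little-endian 16-bit samples.
# EDF+ adds an "EDF Annotations" signal whose samples are raw bytes
# carrying time-stamped annotation lists (TALs):
#   +onset[\x15duration]\x14label\x14\x00
# Every record starts with a bare timekeeping TAL (+recordonset\x14\x14).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)
}

edf_num <- function(x) {
  # shortest decimal representation that fits an 8-char header field
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > 8) s <- substr(s, 1, 8)
  s
}

# canonical 10-20 names; modern temporal names map onto the old ones
canonical_1020_map <- function() {
  nm <- electrodes_1020()
  map <- stats::setNames(nm, tolower(nm))
  c(map, t7 = "T3", t8 = "T4", p7 = "T5", p8 = "T6")
}

reference_suffixes <- c("ref", "le", "re", "a1", "a2", "avg", "av", "m1", "m2")

#' Normalize an EDF channel label to a bare 10-20 electrode name
#'
#' Strips an `"EEG "` prefix and a reference suffix (`"-Ref"`, `"-A1"`,
#' ...), and canonicalizes modern temporal names (T7/T8/P7/P8) to the old
#' nomenclature (T3/T4/T5/T6). Labels that do not resolve to a 10-20
#' electrode are returned trimmed but otherwise untouched.
#'
#' @param label character vector of raw EDF signal labels.
#' @return character vector of normalized labels.
#' @export
normalize_channel_label <- function(label) {
  canonical_1020 <- canonical_1020_map()
  vapply(label, function(lb) {
    s <- trimws(lb)
    s <- sub("^EEG[ _]+", "", s, ignore.case = TRUE)
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) == 2 && tolower(trimws(parts[2])) %in% reference_suffixes)
      s <- trimws(parts[1])
    hit <- canonical_1020[tolower(s)]
    if (!is.na(hit)) unname(hit) else s
  }, character(1), USE.NAMES = FALSE)
}

format_tal <- function(onset, duration = NULL, label = NULL) {
  s <- sprintf("+%.6f", onset)
  if (!is.null(duration)) s <- paste0(s, "\x15", sprintf("%.6f", duration))
  # a timekeeping TAL (no label) carries an empty annotation: onset,
  # x14, x14; an event TAL is onset [x15 duration] x14 label x14
  s <- if (is.null(label)) paste0(s, "\x14\x14")
  else paste0(s, "\x14", label, "\x14")
  charToRaw(s)
}

#' Write a recording to an EDF(+) file
#'
#' Signals are quantized to 16 bits over a symmetric per-channel physical
#' range in microvolts; annotations are stored in an EDF+ annotation
#' signal. Record duration is one second, so the signal length is
#' truncated to whole seconds (with a warning) if needed.
#'
#' @param recording an [eeg_recording()] or [eeg_bipolar()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signal
  fs <- recording$sfreq
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  n_records <- floor(ncol(sig) / fs)
  if (n_records < 1) stop("recording shorter than one EDF record (1 s)")
  if (n_records * fs < ncol(sig)) {
    warning("signal truncated to whole seconds for EDF record layout")
    sig <- sig[, seq_len(n_records * fs), drop = FALSE]
  }
  nch <- nrow(sig)
  ann <- recording$annotations

  # 16-bit quantization over a symmetric per-channel range
  phys_max <- pmax(ceiling(apply(abs(sig), 1, max)), 1)
  dmin <- -32768; dmax <- 32767
  dig <- matrix(0L, nch, ncol(sig))
  for (k in seq_len(nch)) {
    scale <- (2 * phys_max[k]) / (dmax - dmin)
    d <- round((sig[k, ] + phys_max[k]) / scale + dmin)
    dig[k, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }

  # per-record annotation byte streams
  rec_of_onset <- pmin(pmax(floor(ann$onset), 0), n_records - 1)
  tal_bytes <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    chunks <- list(format_tal(r - 1), as.raw(0))
    hit <- which(rec_of_onset == r - 1)
    for (i in hit) {
      chunks <- c(chunks,
                  list(format_tal(ann$onset[i], ann$duration[i], ann$label[i]),
                       as.raw(0)))
    }
    tal_bytes[[r]] <- do.call(c, chunks)
  }
  ann_bytes <- max(60L, max(vapply(tal_bytes, length, 0L)))
  ann_samples <- as.integer(ceiling(ann_bytes / 2))

  labels <- vapply(rownames(sig), function(nm) {
    if (nm %in% electrodes_1020()) paste0("EEG ", nm, "-Ref") else nm
  }, character(1))

  ns <- nch + 1L   # plus the annotation signal
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad_field(x, width)), con)

  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # local patient id
  wr(paste("Startdate 01-JAN-2020 X X", recording$recording_id), 80)
  wr("01.01.20", 8)                            # start date
  wr("00.00.00", 8)                            # start time
  wr(256L * (ns + 1L), 8)                      # header bytes
  wr("EDF+C", 44)                              # reserved: EDF+ continuous
  wr(n_records, 8)
  wr("1", 8)                                   # record duration, seconds
  wr(ns, 4)

  all_labels <- c(labels, "EDF Annotations")
  for (lb in all_labels) wr(lb, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num(-phys_max[i]) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) edf_num(phys_max[i]) else "1", 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(if (i <= nch) fs else ann_samples, 8)
  for (i in seq_len(ns)) wr("", 32)            # signal reserved

  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
    tal <- tal_bytes[[r]]
    pad <- raw(2L * ann_samples - length(tal))
    writeBin(c(tal, pad), con)
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF or EDF(+) file
#'
#' Returns signals in physical units (microvolts), channel labels
#' normalized to bare 10-20 names via [normalize_channel_label()], and
#' annotations parsed from the EDF+ annotation signal. Non-EEG signals
#' whose sampling rate differs from the EEG rate are dropped silently.
#'
#' @param path path to an EDF/EDF+ file.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 256) stop("corrupt EDF header: file too short")

  version <- read_header_field(raw_all, 0, 8)
  if (version != "0") stop("corrupt EDF header: unknown version '", version, "'")
  header_bytes <- as.integer(read_header_field(raw_all, 184, 8))
  n_records <- as.integer(read_header_field(raw_all, 236, 8))
  record_dur <- as.numeric(read_header_field(raw_all, 244, 8))
  ns <- as.integer(read_header_field(raw_all, 252, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records))
    stop("corrupt EDF header: bad signal/record counts")

  fld <- function(base, width, i) {
    read_header_field(raw_all, 256 + base * ns + (i - 1) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) fld(96 + 8, 8, i), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) fld(96 + 16, 8, i), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) fld(96 + 24, 8, i), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) fld(96 + 32, 8, i), character(1)))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) fld(96 + 40 + 80, 8, i), character(1)))

  is_ann <- labels == "EDF Annotations"
  data_raw <- raw_all[(header_bytes + 1):length(raw_all)]
  rec_samples <- sum(nsamp)
  expected <- 2 * rec_samples * n_records
  if (length(data_raw) < expected)
    stop("corrupt EDF file: data shorter than header promises")
  sig_offsets <- c(0L, cumsum(nsamp))   # sample offsets within a record

  eeg_idx <- which(!is_ann)
  rates <- nsamp[eeg_idx] / record_dur
  main_rate <- as.numeric(names(sort(table(rates), decreasing = TRUE))[1])
  keep <- eeg_idx[rates == main_rate]

  n_per_ch <- nsamp[keep[1]] * n_records
  signal <- matrix(0, length(keep), n_per_ch)
  rec_byte_offsets <- (seq_len(n_records) - 1L) * rec_samples * 2L
  for (j in seq_along(keep)) {
    i <- keep[j]
    within <- (sig_offsets[i] * 2L) + seq_len(nsamp[i] * 2L)
    byte_idx <- as.vector(outer(within, rec_byte_offsets, `+`))
    dig <- readBin(data_raw[byte_idx], "integer", n = nsamp[i] * n_records,
                   size = 2, signed = TRUE, endian = "little")
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    signal[j, ] <- (dig - dig_min[i]) * scale + phys_min[i]
  }
  rownames(signal) <- normalize_channel_label(labels[keep])

  annotations <- empty_annotations()
  for (i in which(is_ann)) {
    within <- (sig_offsets[i] * 2L) + seq_len(nsamp[i] * 2L)
    byte_idx <- as.vector(outer(within, rec_byte_offsets, `+`))
    annotations <- rbind(annotations, parse_tals(data_raw[byte_idx]))
  }
  if (nrow(annotations))
    annotations <- annotations[order(annotations$onset), , drop = FALSE]
  rownames(annotations) <- NULL

  eeg_recording(signal, main_rate, annotations,
                recording_id = sub("\\.edf$", "", basename(path),
                                   ignore.case = TRUE))
}

# Parse a stream of TAL bytes into an annotation data frame; bare
# timekeeping TALs (no label) are skipped.
parse_tals <- function(bytes) {
  out <- empty_annotations()
  if (!length(bytes)) return(out)
  zero <- bytes == as.raw(0)
  grp <- cumsum(c(TRUE, zero[-length(zero)]))
  chunks <- split(bytes[!zero], grp[!zero])
  for (ch in chunks) {
    if (!length(ch)) next
    txt <- rawToChar(ch)
    parts <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next            # timekeeping TAL
    head_part <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_part[1]))
    if (is.na(onset)) next
    duration <- if (length(head_part) > 1)
      suppressWarnings(as.numeric(head_part[2])) else 0
    for (lb in parts[-1]) {
      if (nzchar(trimws(lb)))
        out <- rbind(out, data.frame(onset = onset, duration = duration,
                                     label = trimws(lb),
                                     stringsAsFactors = FALSE))
    }
  }
  out
}

#' Summarize an EDF file
#'
#' Prints channels, sampling rate, duration, and annotation count; the
#' `inspect` CLI subcommand wraps this.
#'
#' @param path path to an EDF/EDF+ file.
#' @return invisibly, the [eeg_recording()].
#' @export
inspect_edf <- function(path) {
  rec <- read_edf(path)
  cat(sprintf("%s: %d channels @ %g Hz, %.1f s, %d annotations\n",
              basename(path), nrow(rec$signal), rec$sfreq,
              recording_duration(rec), nrow(rec$annotations)))
  cat("channels:", paste(rec$channels, collapse = " "), "\n")
  invisible(rec)
}
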