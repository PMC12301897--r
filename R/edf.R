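# Minimal European Data Format (EDF) I/O: 16-bit integer samples with linear
# physical scaling, one-second data records. Covers exactly what the pipeline
# needs (continuous multichannel EEG in microvolts); EDF+ annotations,
# discontinuous files and sub-second records are out of scope.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = "-")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over the stated physical range.
#'
#' @param signal channels x samples matrix, microvolts.
#' @param path output file.
#' @param sfreq integer sampling frequency, Hz (one-second data records).
#' @param channel_names labels for the rows of `signal`.
#' @param phys_range physical range in microvolts mapped onto the 16-bit
#'   digital range (default `c(-1000, 1000)`).
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path, sfreq, channel_names = rownames(signal),
                      phys_range = c(-1000, 1000),
                      patient = "X", recording = "X") {
  stopifnot(is.matrix(signal), nrow(signal) == length(channel_names))
  if (sfreq != round(sfreq))
    stop("write_edf requires an integer sampling frequency", call. = FALSE)
  ns <- nrow(signal)
  spr <- as.integer(sfreq)           # samples per record (1 s records)
  n_rec <- floor(ncol(signal) / spr)
  if (n_rec < 1) stop("signal shorter than one data record", call. = FALSE)
  if (n_rec * spr < ncol(signal))
    warning("truncating ", ncol(signal) - n_rec * spr,
            " samples beyond the last whole data record")
  dig_min <- -32768; dig_max <- 32767
  scale <- (phys_range[2] - phys_range[1]) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4),
    paste(vapply(channel_names, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),          # transducer
    paste(rep(pad_field("uV", 8), ns), collapse = ""),         # phys dim
    paste(rep(num_field(phys_range[1], 8), ns), collapse = ""),
    paste(rep(num_field(phys_range[2], 8), ns), collapse = ""),
    paste(rep(num_field(dig_min, 8), ns), collapse = ""),
    paste(rep(num_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),          # prefilter
    paste(rep(num_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  clipped <- pmin(pmax(signal, phys_range[1]), phys_range[2])
  dig <- round((clipped - phys_range[1]) / scale) + dig_min
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_header_field <- function(con, width) trimws(readChar(con, width))

#' Read an EDF file
#'
#' Returns the signal in physical units with channel labels normalized to
#' canonical 10-20 names where possible (see [normalize_channel_label()]).
#'
#' @param path EDF file.
#' @return list with `signal` (channels x samples, physical units), `sfreq`,
#'   `channel_names` (normalized), `channel_names_raw`, `patient`,
#'   `recording`, `duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_header_field(con, 8)
  if (version != "0") stop("malformed EDF: bad version field", call. = FALSE)
  patient <- read_header_field(con, 80)
  recording <- read_header_field(con, 80)
  readChar(con, 16)                      # start date/time
  header_bytes <- as.integer(read_header_field(con, 8))
  readChar(con, 44)
  n_rec <- as.integer(read_header_field(con, 8))
  rec_dur <- as.numeric(read_header_field(con, 8))
  ns <- as.integer(read_header_field(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1)
    stop("malformed EDF: bad header counts", call. = FALSE)
  rd <- function(width) vapply(seq_len(ns), function(i)
    read_header_field(con, width), "")
  labels <- rd(16)
  rd(80)                                 # transducer
  rd(8)                                  # physical dimension
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  rd(80)                                 # prefilter
  spr <- as.integer(rd(8))
  rd(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)))
    stop("malformed EDF: unparsable signal headers", call. = FALSE)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  total <- sum(spr) * n_rec
  raw <- readBin(con, integer(), n = total, size = 2, signed = TRUE,
                 endian = "little")
  if (length(raw) < total)
    stop("malformed EDF: truncated data section", call. = FALSE)
  sig <- matrix(0, ns, spr[1] * n_rec)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      sig[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        raw[(pos + 1):(pos + spr[s])]
      pos <- pos + spr[s]
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sweep(sweep(sig, 1, dig_min) * scale, 1, phys_min, `+`)
  sfreq <- spr[1] / rec_dur
  rownames(sig) <- normalize_channel_label(labels)
  list(signal = sig, sfreq = sfreq,
       channel_names = normalize_channel_label(labels),
       channel_names_raw = labels, patient = patient, recording = recording,
       duration_s = n_rec * rec_dur)
}

# canonical 21-electrode 10-20 set (clinical EEG naming)
TEN_TWENTY_21 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "A1", "T3", "C3", "Cz", "C4", "T4", "A2",
                   "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Normalize EEG channel labels to canonical 10-20 names
#'
#' Accepts clinical dialects such as `"EEG FP1-REF"` or `"EEG O1-LE"`:
#' the `EEG` prefix and `-REF`/`-LE` reference suffixes are stripped and the
#' remainder matched case-insensitively against the canonical 21-electrode
#' set. Unrecognized labels are returned trimmed but otherwise unchanged.
#'
#' @param labels character vector of raw labels.
#' @return character vector of normalized labels.
#' @export
normalize_channel_label <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]+", "", x, ignore.case = TRUE)
  x <- sub("-(REF|LE)$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  idx <- match(toupper(x), toupper(TEN_TWENTY_21))
  out <- ifelse(is.na(idx), x, TEN_TWENTY_21[idx])
  out
}
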