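# Minimal European Data Format (EDF) writer and reader.
#
# EDF stores an ASCII header (256 bytes plus 256 per signal) followed by
# data records of 16-bit little-endian integers, one record per second here.
# Only the continuous-signal subset needed for fixture round-trips is
# implemented: equal sampling rate across signals and integer-second
# recordings. Physical calibration is linear between the physical and
# digital extrema declared in the header.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are clipped to the physical range and quantized to 16 bits, so
#' the round-trip error is bounded by half a digital step,
#' `phys_range / 2^15` at the default +/-500 microvolt range.
#'
#' @param rec An [eeg_recording()]. `fs` must be integer-valued and the
#'   sample count a multiple of `fs` (whole seconds).
#' @param path Output file path.
#' @param phys_range Physical half-range in microvolts (default 500).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, phys_range = 500) {
  if (!inherits(rec, "eeg_recording")) stopf("'rec' must be an eeg_recording")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("write_edf: fs must be integer-valued")
  fs <- as.integer(round(fs))
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0) stopf("write_edf: sample count must be a whole number of seconds")
  n_rec <- n_samp %/% fs
  ns <- nrow(rec$data)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("dreamsift synthetic", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  field <- function(vals, width) paste0(vapply(vals, edf_pad, "", width = width),
                                        collapse = "")
  hdr <- paste0(
    hdr,
    field(rec$channel_names, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(rep(-phys_range, ns), 8),
    field(rep(phys_range, ns), 8),
    field(rep(-32767L, ns), 8),
    field(rep(32767L, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale <- 32767 / phys_range
  clipped <- pmin(pmax(rec$data, -phys_range), phys_range)
  dig <- matrix(as.integer(round(clipped * scale)), nrow = ns)
  # record-major layout: for each second, each signal's fs samples in turn
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the header, decodes the 16-bit records and rescales to physical
#' units. Requires equal sampling rates across signals.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] with `reference = "raw"`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("read_edf: file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                  # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  as.integer(rd(8))                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) stopf("read_edf: unequal per-signal rates unsupported")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
      data[s, cols] <- raw[(pos + 1):(pos + spr[s])]
      pos <- pos + spr[s]
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(data, 1, gain, `*`) + (phys_min - dig_min * gain)
  eeg_recording(data, fs, labels, subject_id, reference = "raw")
}
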