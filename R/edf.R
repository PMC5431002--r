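# Minimal single-channel EDF support.
#
# EDF stores 16-bit integers with a linear physical/digital calibration per
# signal, in fixed-duration data records.  Only what this package needs is
# implemented: one signal, 1-second data records, zero-padded final record.

edf_pad <- function(x, width) {
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a single-channel EDF file
#'
#' Samples are linearly quantized to 16-bit integers over the data range
#' (quantization error at most one part in 65535 of the physical span).
#' The recording is split into 1-second data records; the final record is
#' zero-padded, so a reader sees `ceiling(n / fs) * fs` samples.
#'
#' @param samples numeric vector, microvolts.
#' @param fs_hz sampling rate in Hz (integer-valued).
#' @param path output path.
#' @param label signal label written to the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(samples, fs_hz, path, label = "EEG hippocampus") {
  stopifnot(fs_hz > 0, fs_hz == round(fs_hz), length(samples) >= 1)
  n_rec <- ceiling(length(samples) / fs_hz)
  padded <- c(samples, rep(0, n_rec * fs_hz - length(samples)))
  pmin <- min(padded); pmax <- max(padded)
  if (pmax == pmin) { pmin <- pmin - 1; pmax <- pmax + 1 }
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((padded - pmin) / (pmax - pmin) *
                            (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),      # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 + 256), 8),   # header bytes: 256 + ns*256
    edf_pad("", 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad("1", 8),                       # record duration (s)
    edf_pad("1", 4))                       # number of signals
  sig <- paste0(
    edf_pad(label, 16), edf_pad("AgAgCl electrode", 80), edf_pad("uV", 8),
    edf_pad(format(pmin, digits = 7), 8),
    edf_pad(format(pmax, digits = 7), 8),
    edf_pad(as.character(dmin), 8), edf_pad(as.character(dmax), 8),
    edf_pad("", 80), edf_pad(as.character(fs_hz), 8), edf_pad("", 32))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' @param path path to an EDF file containing exactly one signal (files with
#'   more than one signal are rejected; pre-select a channel upstream).
#' @return list with `samples` (microvolts), `fs_hz`, and `label`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.numeric(field(hdr, 237, 8))
  rec_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns != 1L)
    stop("EDF file must contain exactly one signal (found ", ns,
         "); no channel selector is supported", call. = FALSE)
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  label <- field(sig, 1, 16)
  pmin <- as.numeric(field(sig, 105, 8))
  pmax <- as.numeric(field(sig, 113, 8))
  dmin <- as.numeric(field(sig, 121, 8))
  dmax <- as.numeric(field(sig, 129, 8))
  spr <- as.integer(field(sig, 217, 8))
  dig <- readBin(con, integer(), n = n_rec * spr, size = 2, signed = TRUE,
                 endian = "little")
  samples <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  list(samples = samples, fs_hz = spr / rec_dur, label = label)
}
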