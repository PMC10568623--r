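# Minimal EDF (European Data Format, 16-bit) reader/writer: fixed 256-byte
# header plus 256 bytes per signal, then data records of little-endian 16-bit
# integers. Enough to round-trip the recordings this pipeline works with;
# annotations, EDF+ and discontinuous records are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' @param rec an [eeg_recording()] (microvolt data).
#' @param path output file.
#' @param record_duration data-record length in seconds (default 1; must give
#'   an integer number of samples). Trailing samples that do not fill a whole
#'   record are dropped.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- rec$sfreq * record_duration
  sn_assert(abs(spr - round(spr)) < 1e-9,
            "record_duration * sfreq must be an integer", "invalid_parameter")
  spr <- as.integer(round(spr))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% spr
  sn_assert(n_rec >= 1, "recording shorter than one data record",
            "invalid_parameter")
  pmax_ <- max(1e-6, max(abs(rec$data)))
  pmin_ <- -pmax_
  dmax <- 32767L
  dmin <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("strokenet synthetic recording", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(format(record_duration), 8)
  wr(ns, 4)
  for (l in rec$channel_labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_, digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_, digits = 6), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    block <- rec$data[, idx, drop = FALSE]
    dig <- round((block - pmin_) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written by [write_edf()] or another standard
#'   16-bit EDF source.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  sn_assert(length(unique(spr)) == 1,
            "mixed per-signal sampling rates are not supported", "invalid_input")
  spr1 <- spr[1]
  data <- matrix(0, ns, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr1, size = 2, endian = "little")
    block <- matrix(raw, nrow = spr1, ncol = ns)
    idx <- ((r - 1) * spr1 + 1):(r * spr1)
    for (s in seq_len(ns)) {
      data[s, idx] <- pmin_[s] +
        (block[, s] - dmin[s]) * (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
    }
  }
  eeg_recording(data, labels, sfreq = spr1 / rec_dur, subject_id = subject_id)
}
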