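# Minimal EDF (European Data Format) writer/reader for multichannel EEG.
# 16-bit little-endian samples, one-second data records. Covers the plain
# EDF subset this package emits (no annotations, equal rate per channel).

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel into the 16-bit digital range; the
#' physical range stored in the header is the channel's data range, so the
#' quantization step is (max - min) / 65535 uV.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"), rec$fs == round(rec$fs))
  x <- rec$data
  ns <- nrow(x)
  spr <- as.integer(rec$fs)
  nrec <- ncol(x) %/% spr
  stopifnot(nrec >= 1)
  x <- x[, seq_len(nrec * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate 01-JAN-2000", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rec$labels, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(sprintf("%.8g", pmin_), 8)
  fld(sprintf("%.8g", pmax_), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)
  fld(rep(spr, ns), 8)
  fld(rep("", ns), 32)
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, idx] - pmin_[ch]) * scale[ch]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param condition Optional condition tag to attach.
#' @return An [recording()] (block onset at sample 1).
#' @export
read_edf <- function(path, condition = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0.0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0.0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0.0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0.0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / dur
  out <- matrix(NA_real_, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      phys <- pmin_[ch] + (dig - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  recording(out, fs, labels, condition = condition)
}
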