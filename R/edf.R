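#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one data record
#' spanning the whole signal. The physical range is auto-scaled per channel
#' so arbitrary synthetic amplitudes round-trip within one quantization
#' step. Channel annotations are not stored in the file; keep them in the
#' channel map.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$data
  nc <- nrow(x); ns <- ncol(x)
  if (ns < 1L) stop("empty recording")
  dmin <- -32767L; dmax <- 32767L
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- (pmax - pmin) <= 0
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(format(s), 1, w)
    sprintf("%-*s", w, s)
  }
  num <- function(v, w) vapply(v, function(z) pad(formatC(z, digits = 6,
    format = "g", flag = ""), w), character(1))
  hdr <- paste0(
    pad("0", 8), pad("synthetic", 80), pad(paste(rec$modality[1], "iednet"), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256L + 256L * nc, 8), pad(paste0("fs=", format(rec$fs)), 44),
    pad(1L, 8), pad(formatC(ns / rec$fs, digits = 6, format = "g"), 8),
    pad(nc, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(rec$labels, pad, character(1), w = 16), collapse = ""),
    paste(rep(pad("", 80), nc), collapse = ""),
    paste(rep(pad("uV", 8), nc), collapse = ""),
    paste(num(pmin, 8), collapse = ""),
    paste(num(pmax, 8), collapse = ""),
    paste(rep(pad(dmin, 8), nc), collapse = ""),
    paste(rep(pad(dmax, 8), nc), collapse = ""),
    paste(rep(pad("", 80), nc), collapse = ""),
    paste(rep(pad(ns, 8), nc), collapse = ""),
    paste(rep(pad("", 32), nc), collapse = "")
  )
  writeChar(sig, con, eos = NULL)
  for (i in seq_len(nc)) {
    dig <- round((x[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads 16-bit EDF with any record layout written by [write_recording()]
#' or other tools (multiple fixed-duration records are concatenated).
#'
#' @param path EDF file path.
#' @param modality Modality tag to attach (`"scalp"` or `"intracranial"`).
#' @return A [recording()].
#' @export
read_recording <- function(path, modality = "scalp") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1L) stop("unreadable EDF header (no signals)")
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  if (anyDuplicated(labels)) stop("duplicate channel labels in EDF file")
  for (i in seq_len(nc)) rd(80)               # transducer
  for (i in seq_len(nc)) rd(8)                # physical dimension
  pmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)               # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)               # reserved
  if (length(unique(spr / rec_dur)) != 1L) {
    stop("channels with different sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = nc, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L,
                     endian = "little")
      if (length(dig) != spr[i]) stop("inconsistent channel lengths")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
        pmin[i]
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  recording(out, fs = fs, labels = labels, modality = modality)
}

#' Quantization step of the EDF representation of a recording
#'
#' @param rec A [recording()].
#' @return Per-channel physical value of one 16-bit digital step.
#' @export
edf_quantization_step <- function(rec) {
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  rng <- pmax - pmin
  rng[rng <= 0] <- 2
  rng / (32767 - (-32767))
}
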