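# Minimal European Data Format (EDF) support: fixed 256-byte ASCII header,
# 256 bytes per signal of per-signal headers, then 16-bit little-endian
# samples grouped channel-block by data record. Covers equal-rate continuous
# signals, which is all this package produces or consumes.

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write an EEG recording as a 16-bit EDF file
#'
#' Samples are linearly quantized per channel into the signed 16-bit digital
#' range, so a read-back differs from the original by at most one quantization
#' step of \code{(max - min) / 65535} per channel.
#'
#' @param rec an \code{eeg_recording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  nc <- n_channels(rec); ns <- n_samples(rec)
  # one-second records where possible, else a single record holding everything
  if (rec$fs == round(rec$fs) && ns %% rec$fs == 0) {
    spr <- as.integer(rec$fs); n_rec <- ns %/% spr; rec_dur <- 1
  } else {
    spr <- ns; n_rec <- 1L; rec_dur <- ns / rec$fs
  }
  pmin <- apply(rec$data, 1L, min); pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8L),                       # version
    pad_field(rec$subject_id, 80L),           # patient id
    pad_field("msnetvar recording", 80L),     # recording id
    pad_field("01.01.00", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (nc + 1L), 8L),          # header bytes
    pad_field("", 44L),
    pad_field(n_rec, 8L),
    pad_field(format(rec_dur, digits = 7), 8L),
    pad_field(nc, 4L)), con, eos = NULL)
  writeChar(paste0(
    paste(pad_field(rec$channels, 16L), collapse = ""),
    paste(pad_field(rep("", nc), 80L), collapse = ""),   # transducer
    paste(pad_field(rep("uV", nc), 8L), collapse = ""),  # physical dimension
    paste(pad_field(format(pmin, digits = 7), 8L), collapse = ""),
    paste(pad_field(format(pmax, digits = 7), 8L), collapse = ""),
    paste(pad_field(rep(dmin, nc), 8L), collapse = ""),
    paste(pad_field(rep(dmax, nc), 8L), collapse = ""),
    paste(pad_field(rep("", nc), 80L), collapse = ""),   # prefiltering
    paste(pad_field(rep(spr, nc), 8L), collapse = ""),
    paste(pad_field(rep("", nc), 32L), collapse = "")), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round(sweep(sweep(rec$data, 1L, pmin), 1L, scale, "*")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF file path.
#' @return A list with \code{data} (channels x samples matrix, physical
#'   units), \code{fs}, \code{channels}, \code{subject_id}.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  subject_id <- fld(hdr, 9L, 80L)
  n_rec <- as.integer(fld(hdr, 237L, 8L))
  rec_dur <- as.numeric(fld(hdr, 245L, 8L))
  nc <- as.integer(fld(hdr, 253L, 4L))
  if (is.na(nc) || nc < 1L) stop("not a readable EDF file: ", path)
  sig <- readChar(con, 256L * nc, useBytes = TRUE)
  seg <- function(block_off, width, i)
    trimws(substr(sig, block_off + (i - 1L) * width + 1L,
                  block_off + i * width))
  channels <- vapply(seq_len(nc), function(i) seg(0L, 16L, i), character(1L))
  off_pmin <- nc * (16L + 80L + 8L)
  pmin <- as.numeric(vapply(seq_len(nc), function(i) seg(off_pmin, 8L, i), character(1L)))
  pmax <- as.numeric(vapply(seq_len(nc), function(i) seg(off_pmin + 8L * nc, 8L, i), character(1L)))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) seg(off_pmin + 16L * nc, 8L, i), character(1L)))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) seg(off_pmin + 24L * nc, 8L, i), character(1L)))
  off_spr <- off_pmin + 32L * nc + 80L * nc
  spr <- as.integer(vapply(seq_len(nc), function(i) seg(off_spr, 8L, i), character(1L)))
  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  spr <- spr[1L]
  fs <- spr / rec_dur
  raw <- readBin(con, integer(), n = nc * spr * n_rec, size = 2L,
                 endian = "little", signed = TRUE)
  dat <- matrix(0, nc, spr * n_rec)
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1L) * nc * spr + 1L):(r * nc * spr)],
                    nrow = spr, ncol = nc)
    dat[, ((r - 1L) * spr + 1L):(r * spr)] <- t(block)
  }
  phys <- sweep(sweep(dat, 1L, dmin), 1L, (pmax - pmin) / (dmax - dmin), "*")
  phys <- sweep(phys, 1L, pmin, "+")
  list(data = phys, fs = fs, channels = channels, subject_id = subject_id)
}
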