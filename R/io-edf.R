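# Minimal EDF (European Data Format) reader/writer: 16-bit samples, ASCII
# header, one-second data records, a single sampling rate across channels.
# EDF+ annotation streams and BDF are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  assert_that(nchar(x) <= width,
              paste0("EDF header field too long: '", x, "'"))
  formatC(x, width = -width)  # left-justified, space-padded
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 4), 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. Each channel gets a
#' symmetric physical range covering its data; samples are quantized to the
#' 16-bit digital range, so a read-back agrees with the original within half
#' a quantization step. The sampling rate must be a whole number of samples
#' per second, and any trailing partial second is dropped.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  assert_that(inherits(recording, "eeg_recording"),
              "`recording` must be an eeg_recording")
  fs <- recording$sampling_rate
  assert_that(fs == round(fs), "EDF writer requires an integer sampling rate")
  ns <- nrow(recording$data)
  n_rec <- floor(ncol(recording$data) / fs)
  assert_that(n_rec >= 1, "recording shorter than one EDF record (1 s)")
  keep <- seq_len(n_rec * fs)
  data <- recording$data[, keep, drop = FALSE]

  pmax_ <- apply(abs(data), 1, max)
  pmax_ <- pmax(ceiling(pmax_ * 10) / 10, 1)  # avoid zero-width ranges
  pmin_ <- -pmax_
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  field <- function(values, width) paste0(vapply(values, edf_pad, "", width = width), collapse = "")
  nfield <- function(values, width) paste0(vapply(values, edf_num, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(recording$channel_names, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    nfield(pmin_, 8),
    nfield(pmax_, 8),
    field(rep(dmin, ns), 8),
    field(rep(dmax, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale_ <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * scale_[ch] + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Parses the EDF header, converts 16-bit digital samples back to physical
#' units, and normalizes channel labels (see [normalize_channel_name()]).
#' Files whose channels disagree on samples-per-record (i.e. sampling rate)
#' are rejected.
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  sz <- file.info(path)$size
  assert_that(is.finite(sz) && sz >= 256, "not a valid EDF file: header truncated")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  assert_that(version == "0", "not a valid EDF file: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns >= 1, "not a valid EDF file: bad signal count")
  assert_that(!is.na(n_rec) && n_rec >= 1, "EDF file has no data records")
  assert_that(is.finite(rec_dur) && rec_dur > 0, "bad record duration")
  assert_that(sz >= hdr_bytes, "EDF header truncated")

  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)                       # transducer
  rdv(8)                        # physical dimension
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                       # prefiltering
  nspr <- as.integer(rdv(8))
  rdv(32)                       # reserved
  assert_that(!anyNA(c(pmin_, pmax_, dmin, dmax, nspr)),
              "malformed EDF signal header")
  assert_that(length(unique(nspr)) == 1,
              "inconsistent per-channel sampling rates are not supported")
  fs <- nspr[1] / rec_dur

  n <- n_rec * nspr[1]
  data <- matrix(0, nrow = ns, ncol = n)
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nspr[ch], size = 2,
                     endian = "little", signed = TRUE)
      assert_that(length(dig) == nspr[ch], "EDF data truncated")
      idx <- ((r - 1) * nspr[ch] + 1):(r * nspr[ch])
      data[ch, idx] <- (dig - dmin[ch]) * scale_[ch] + pmin_[ch]
    }
  }
  eeg_recording(data, normalize_channel_name(labels), fs)
}
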