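# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, scaled per channel between the
# header's physical and digital extrema. The writer emits a single data
# record holding the whole recording (valid EDF; sidesteps the constraint
# that the sample count divide into fixed-duration records), and carries the
# referencing and unit state in the header's reserved field so that a
# roundtrip restores them. The artifact mask is not part of EDF and is not
# persisted here.

fit_ascii <- function(x, width) {
  if (is.character(x)) {
    s <- x
    if (nchar(s) > width) stopf("header field too long: %s", s)
  } else {
    s <- NA_character_
    for (d in seq(12, 1)) {
      cand <- formatC(x, digits = d, format = "g", width = 1)
      if (nchar(cand) <= width) { s <- cand; break }
    }
    if (is.na(s)) stopf("cannot fit %g in %d ASCII chars", x, width)
  }
  formatC(s, width = -width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16 bits between each channel's physical minimum
#' and maximum, so the roundtrip error is bounded by one quantisation step.
#'
#' @param rec An [new_recording()] object. All channels share `rec$fs`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  if (ns == 0) stopf("empty channel list")
  n <- ncol(rec$data)
  if (n == 0) stopf("recording has no samples")
  dur <- n / rec$fs
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(fit_ascii("0", 8))
  wr(fit_ascii("X", 80))
  wr(fit_ascii("X", 80))
  wr(fit_ascii("01.01.01", 8))
  wr(fit_ascii("00.00.00", 8))
  wr(fit_ascii(256 * (ns + 1), 8))
  wr(fit_ascii(sprintf("ref=%s;unit=%s", rec$reference, rec$unit_state), 44))
  wr(fit_ascii(1, 8))                      # one data record
  wr(fit_ascii(dur, 8))
  wr(fit_ascii(ns, 4))
  for (lab in rec$labels) wr(fit_ascii(lab, 16))
  for (i in seq_len(ns)) wr(fit_ascii("", 80))   # transducer
  unit <- if (rec$unit_state == "volts") "uV" else ""
  for (i in seq_len(ns)) wr(fit_ascii(unit, 8))
  for (i in seq_len(ns)) wr(fit_ascii(pmin[i], 8))
  for (i in seq_len(ns)) wr(fit_ascii(pmax[i], 8))
  for (i in seq_len(ns)) wr(fit_ascii(-32768, 8))
  for (i in seq_len(ns)) wr(fit_ascii(32767, 8))
  for (i in seq_len(ns)) wr(fit_ascii("", 80))   # prefilter
  for (i in seq_len(ns)) wr(fit_ascii(n, 8))     # samples per record
  for (i in seq_len(ns)) wr(fit_ascii("", 32))
  # header physical extrema as re-parsed, so scaling matches the reader
  pmin_h <- as.numeric(vapply(pmin, fit_ascii, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, fit_ascii, "", width = 8))
  for (i in seq_len(ns)) {
    scale <- (pmax_h[i] - pmin_h[i]) / 65535
    dig <- as.integer(round((rec$data[i, ] - pmin_h[i]) / scale) - 32768)
    dig[dig > 32767L] <- 32767L
    dig[dig < -32768L] <- -32768L
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An `eeg_recording` (artifact mask all-usable; bad channels empty).
#'   All channels must share one sampling rate; mixed rates are an error.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    s <- readChar(con, nc, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < nc)
      stopf("malformed EDF header: truncated file")
    trimws(s)
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stopf("malformed EDF header: bad %s field '%s'", what, s)
    v
  }
  version <- rd(8)
  if (version != "0") stopf("malformed EDF header: version '%s'", version)
  rd(80); rd(80); rd(8); rd(8)
  num(rd(8), "header bytes")
  reserved <- rd(44)
  n_rec <- num(rd(8), "record count")
  dur <- num(rd(8), "record duration")
  ns <- as.integer(num(rd(4), "signal count"))
  if (ns < 1) stopf("malformed EDF header: no signals")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) num(rd(8), "physical min"), 0)
  pmax <- vapply(seq_len(ns), function(i) num(rd(8), "physical max"), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8), "digital min"), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8), "digital max"), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(rd(8), "samples/record"), 0)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stopf("mixed sampling rates across channels (samples/record: %s)",
          paste(unique(spr), collapse = ", "))
  spr <- spr[1]
  fs <- spr / dur
  data <- matrix(0, ns, spr * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr, size = 2L, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr) stopf("malformed EDF: truncated data record")
      scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1) * spr + 1):(r * spr)] <- (dig - dmin[i]) * scale + pmin[i]
    }
  }
  reference <- if (grepl("ref=average", reserved)) "average" else "earlobe"
  unit_state <- if (grepl("unit=zscored", reserved)) "zscored" else "volts"
  new_recording(data, fs, labels, reference = reference,
                unit_state = unit_state)
}
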