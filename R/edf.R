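# Minimal European Data Format (EDF) support: 256-byte ASCII main header,
# 256 bytes of ASCII header per signal, then data records of little-endian
# int16 samples scaled linearly between digital and physical ranges.
# Covers continuous single-rate recordings, which is all the pipeline
# consumes; EDF+ annotations are not parsed.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF recording
#'
#' Parses the fixed-layout EDF header, checks that all signals share one
#' sampling rate, converts digital samples to physical units, and
#' returns an [eeg_recording()].
#'
#' @param path Path to an `.edf` file.
#' @param participant_id,run_id Identifiers stamped on the recording.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, participant_id = NA_character_,
                     run_id = NA_character_) {
  if (!file.exists(path))
    stop("read_edf: file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8L)                        # version
  read_ascii(con, 80L); read_ascii(con, 80L) # patient, recording
  read_ascii(con, 8L); read_ascii(con, 8L)   # date, time
  read_ascii(con, 8L)                        # header bytes
  read_ascii(con, 44L)                       # reserved
  n_rec <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("read_edf: bad signal count", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w),
                            character(1))
  labels <- fld(16L)
  fld(80L); fld(8L)                          # transducer, phys dim
  pmin_ <- as.numeric(fld(8L)); pmax_ <- as.numeric(fld(8L))
  dmin_ <- as.numeric(fld(8L)); dmax_ <- as.numeric(fld(8L))
  fld(80L)                                   # prefilter
  spr <- as.integer(fld(8L))
  fld(32L)                                   # reserved
  if (length(unique(spr)) != 1L)
    stop("read_edf: signals with differing sampling rates are not supported",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("read_edf: duplicate channel labels", call. = FALSE)
  sfreq <- spr[1L] / rec_dur
  if (!is.finite(sfreq) || sfreq <= 0)
    stop("read_edf: nonpositive sampling rate", call. = FALSE)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1L], size = 2L, signed = TRUE,
                     endian = "little")
      data[s, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dmin_[s]) * gain[s] + pmin_[s]
    }
  }
  eeg_recording(data, sfreq, channel_names = labels,
                participant_id = participant_id, run_id = run_id)
}

pad <- function(x, w) {
  s <- formatC(as.character(x), width = w, flag = "-")
  if (any(nchar(s) > w))
    stop("write_edf: header field wider than ", w, " bytes", call. = FALSE)
  s
}

# shortest %g representation of a number that fits an 8-byte header field
fmt8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8L) return(s)
    }
    stop("write_edf: value does not fit header field", call. = FALSE)
  }, character(1))
}

#' Write an EDF recording
#'
#' Minimal writer used to export synthetic recordings and to round-trip
#' test [read_edf()].  The physical range is taken from the data; one
#' data record per second.
#'
#' @param rec An [eeg_recording()]; `sfreq` must be a positive integer.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- as.integer(round(rec$sfreq))
  if (abs(spr - rec$sfreq) > 1e-9)
    stop("write_edf: non-integer sampling rates not supported", call. = FALSE)
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1L) stop("write_edf: less than one second of data", call. = FALSE)
  X <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(X, 1L, min); pmax_ <- apply(X, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- -32768L; dmax_ <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8L); wr("X", 80L); wr("X", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(256L * (1L + ns), 8L); wr("", 44L)
  wr(n_rec, 8L); wr("1", 8L); wr(ns, 4L)
  for (s in seq_len(ns)) wr(rec$channel_names[s], 16L)
  for (s in seq_len(ns)) wr("", 80L)
  for (s in seq_len(ns)) wr("uV", 8L)
  pmin_s <- fmt8(pmin_); pmax_s <- fmt8(pmax_)
  for (s in seq_len(ns)) wr(pmin_s[s], 8L)
  for (s in seq_len(ns)) wr(pmax_s[s], 8L)
  for (s in seq_len(ns)) wr(dmin_, 8L)
  for (s in seq_len(ns)) wr(dmax_, 8L)
  for (s in seq_len(ns)) wr("", 80L)
  for (s in seq_len(ns)) wr(spr, 8L)
  for (s in seq_len(ns)) wr("", 32L)
  # quantize against the values as actually written to the header
  pmin_w <- as.numeric(pmin_s)
  pmax_w <- as.numeric(pmax_s)
  gain <- (dmax_ - dmin_) / (pmax_w - pmin_w)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- X[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- as.integer(round((seg - pmin_w[s]) * gain[s] + dmin_))
      writeBin(pmin(dmax_, pmax(dmin_, dig)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
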