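#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-50 Hz.
#' Shared band edges (e.g. 4 Hz) are inclusive on both sides, mirroring
#' inclusive range masks on the PSD grid, so on an edge-aligned grid the
#' five band integrals sum exactly to the 1-50 Hz integral.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Construct an EEG recording
#'
#' Container for continuous preprocessed EEG: a channels x samples
#' matrix, its sampling rate and channel names, plus the participant/run
#' identity used downstream as random-effect grouping factors.
#'
#' @param data Numeric matrix, channels in rows.
#' @param sfreq Sampling frequency in Hz, > 0.
#' @param channel_names Unique channel labels (defaults to `ch1..chk`).
#' @param participant_id,run_id Identifiers.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_names = NULL,
                          participant_id = NA_character_,
                          run_id = NA_character_) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(sfreq), length(sfreq) == 1L)
  if (sfreq <= 0) stop("eeg_recording: sfreq must be > 0", call. = FALSE)
  if (anyNA(data) || !all(is.finite(data)))
    stop("eeg_recording: data contains NaN/Inf after load", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (anyDuplicated(channel_names))
    stop("eeg_recording: duplicate channel names", call. = FALSE)
  if (length(channel_names) != nrow(data))
    stop("eeg_recording: one name per channel required", call. = FALSE)
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names,
                 participant_id = participant_id, run_id = run_id),
            class = "eeg_recording")
}

#' Drop channels by name
#'
#' Montage-specific exclusion (e.g. electrodes near the ears, forehead
#' and back of the head) is configuration, not code: pass the list of
#' labels to drop.
#'
#' @param rec An [eeg_recording()].
#' @param exclude Character vector of channel names to remove.
#' @return The reduced recording.
#' @export
exclude_channels <- function(rec, exclude) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(rec$channel_names %in% exclude)
  if (!any(keep)) stop("exclude_channels: no channels left", call. = FALSE)
  eeg_recording(rec$data[keep, , drop = FALSE], rec$sfreq,
                rec$channel_names[keep], rec$participant_id, rec$run_id)
}

#' Cut a recording into reading epochs at ROWS/ROWE markers
#'
#' Event sample indices are 0-based and epochs are half-open
#' `[start, end)`: ROWS at 100 and ROWE at 612 yield 512 samples.  Each
#' ROWS must be followed by the ROWE of the same unit; violations raise a
#' structured error (class `embedeeg_event_error`) naming the offending
#' unit_ids.  Epochs shorter than `min_duration_s` cannot support the
#' shortest Welch window and are dropped with a message; the count is
#' available as attribute `n_dropped`.
#'
#' @param rec An [eeg_recording()].
#' @param events Data frame with columns `sample_index`, `label`
#'   (ROWS/ROWE), `unit_id`.
#' @param min_duration_s Minimum retained epoch length in seconds.
#' @return List of `eeg_epoch` objects (fields `unit_id`, `data`,
#'   `sfreq`, `duration_s`).
#' @export
extract_epochs <- function(rec, events, min_duration_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"), is.data.frame(events),
            all(c("sample_index", "label", "unit_id") %in% names(events)))
  si <- events$sample_index
  if (is.unsorted(si, strictly = TRUE)) {
    bad <- which(diff(si) <= 0)[1L] + 1L
    stop_event_error(sprintf(
      "event sample indices not strictly increasing at row %d (unit_id=%s)",
      bad, events$unit_id[bad]), events$unit_id[bad])
  }
  lab <- as.character(events$label)
  n <- length(lab)
  bad_units <- character(0)
  if (n %% 2L != 0L)
    bad_units <- as.character(events$unit_id[n])
  pair_ok <- if (n >= 2L) {
    idx <- seq(1L, n - n %% 2L, by = 2L)
    lab[idx] == "ROWS" & lab[idx + 1L] == "ROWE" &
      as.character(events$unit_id[idx]) == as.character(events$unit_id[idx + 1L])
  } else logical(0)
  if (length(pair_ok) && any(!pair_ok))
    bad_units <- unique(c(as.character(events$unit_id[seq(1L, n - n %% 2L,
                                                          by = 2L)][!pair_ok]),
                          bad_units))
  if (length(bad_units))
    stop_event_error(paste0("unmatched ROWS/ROWE markers for unit_id(s): ",
                            paste(bad_units, collapse = ", ")), bad_units)
  ns <- ncol(rec$data)
  starts <- si[seq(1L, n, by = 2L)]
  ends <- si[seq(2L, n, by = 2L)]
  if (length(ends) && max(ends) > ns)
    stop_event_error("event sample index beyond end of recording",
                     as.character(events$unit_id[which.max(si)]))
  uids <- as.character(events$unit_id[seq(1L, n, by = 2L)])
  eps <- lapply(seq_along(starts), function(i) {
    seg <- rec$data[, (starts[i] + 1L):ends[i], drop = FALSE]
    structure(list(unit_id = uids[i], data = seg, sfreq = rec$sfreq,
                   duration_s = ncol(seg) / rec$sfreq),
              class = "eeg_epoch")
  })
  keep <- vapply(eps, function(e) e$duration_s >= min_duration_s, logical(1))
  if (any(!keep))
    message(sum(!keep), " epoch(s) shorter than ", min_duration_s,
            " s dropped")
  structure(eps[keep], n_dropped = sum(!keep))
}

stop_event_error <- function(msg, unit_ids) {
  cnd <- structure(class = c("embedeeg_event_error", "error", "condition"),
                   list(message = paste0("extract_epochs: ", msg),
                        call = NULL, unit_ids = unit_ids))
  stop(cnd)
}

# periodic Hann window, the Welch default
hann <- function(N) 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1L) / N)

#' Welch power spectral density of an epoch
#'
#' Averaged modified periodograms: the epoch is divided into segments of
#' `clamp(duration, win_min_s, win_max_s)` seconds (so epochs shorter
#' than 1 s are analysed with one full-length segment of at least 0.5 s,
#' longer epochs with 1 s segments), each segment is mean-detrended,
#' Hann-windowed, Fourier-transformed, and the one-sided density
#' estimates are averaged across segments.  Consecutive segments overlap
#' by `overlap` (default 50%).  With windows of at least 0.5 s the
#' frequency resolution is at most 2 Hz, so every band edge up to the
#' Nyquist frequency is bracketed by grid points.
#'
#' The density normalization is such that the integral of the PSD over
#' frequency equals signal variance: a pure sinusoid of amplitude A
#' integrates to A^2/2 over its band.
#'
#' @param ep An `eeg_epoch`, or a channels x samples matrix (then `sfreq`
#'   is required).
#' @param sfreq Sampling rate when `ep` is a bare matrix.
#' @param win_min_s,win_max_s Window-length clamp in seconds.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return List with `freqs` (Hz) and `psd` (channels x n_freqs,
#'   units^2/Hz).
#' @export
welch_psd <- function(ep, sfreq = NULL, win_min_s = 0.5, win_max_s = 1,
                      overlap = 0.5) {
  if (inherits(ep, "eeg_epoch")) {
    x <- ep$data; sfreq <- ep$sfreq
  } else {
    x <- as.matrix(ep)
    if (is.null(sfreq)) stop("welch_psd: sfreq required", call. = FALSE)
  }
  ns <- ncol(x)
  dur <- ns / sfreq
  if (dur < win_min_s)
    stop("welch_psd: epoch of ", format(dur), " s is shorter than the ",
         "minimum window of ", win_min_s, " s", call. = FALSE)
  N <- round(min(max(dur, win_min_s), win_max_s) * sfreq)
  N <- min(N, ns)
  step <- max(1L, round(N * (1 - overlap)))
  starts <- seq(1L, ns - N + 1L, by = step)
  w <- hann(N)
  scale <- 1 / (sfreq * sum(w^2))
  nf <- N %/% 2L + 1L
  nch <- nrow(x)
  acc <- matrix(0, nch, nf)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + N - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)            # constant detrend
    seg <- sweep(seg, 2L, w, `*`)
    F <- stats::mvfft(t(seg))             # N x nch
    acc <- acc + t(Mod(F[seq_len(nf), , drop = FALSE])^2)
  }
  psd <- acc / length(starts) * scale
  # one-sided doubling, except DC and (for even N) Nyquist
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (N %% 2L == 0L) dbl[nf] <- 1
  psd <- sweep(psd, 2L, dbl, `*`)
  list(freqs = (seq_len(nf) - 1L) * sfreq / N, psd = psd)
}

# trapezoidal integration on an ascending grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Band power from a PSD
#'
#' Integrates the PSD over each band with the trapezoidal rule, using the
#' grid points whose frequency lies inside `[lo, hi]` (edges inclusive).
#'
#' @param freqs Ascending frequency grid (Hz).
#' @param psd Channels x n_freqs matrix (or a vector for one channel).
#' @param bands Named list of `c(lo, hi)`; default [eeg_bands()].
#' @return Channels x bands matrix of nonnegative powers.
#' @export
band_power <- function(freqs, psd, bands = eeg_bands()) {
  if (is.null(dim(psd))) psd <- matrix(psd, nrow = 1L)
  stopifnot(!is.unsorted(freqs), ncol(psd) == length(freqs))
  nyq <- max(freqs)
  out <- vapply(bands, function(b) {
    if (b[2L] > nyq + 1e-9)
      stop("band_power: band [", b[1L], ", ", b[2L], "] Hz exceeds the ",
           "Nyquist frequency ", nyq, " Hz", call. = FALSE)
    idx <- which(freqs >= b[1L] - 1e-12 & freqs <= b[2L] + 1e-12)
    apply(psd[, idx, drop = FALSE], 1L, function(y) trapz(freqs[idx], y))
  }, numeric(nrow(psd)))
  if (nrow(psd) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, names(bands)))
  out
}

#' Channel-averaged band powers for one epoch
#'
#' @param ep An `eeg_epoch`.
#' @param bands Band definition list.
#' @param participant_id,run_id Identifiers stamped on the row (default
#'   taken from the epoch if present).
#' @param ... Passed to [welch_psd()].
#' @return One-row tibble: `unit_id`, `participant_id`, `run_id`,
#'   `duration_s`, then one column per band (unweighted mean over
#'   channels of the per-channel band power).
#' @export
epoch_band_row <- function(ep, bands = eeg_bands(),
                           participant_id = NA_character_,
                           run_id = NA_character_, ...) {
  stopifnot(inherits(ep, "eeg_epoch"))
  w <- welch_psd(ep, ...)
  bp <- band_power(w$freqs, w$psd, bands)
  avg <- colMeans(bp)
  tibble::tibble(unit_id = ep$unit_id, participant_id = participant_id,
                 run_id = run_id, duration_s = ep$duration_s,
                 !!!stats::setNames(as.list(avg), names(bands)))
}

#' Band-power table for a whole recording
#'
#' Epochs the recording at its ROWS/ROWE markers and emits one
#' channel-averaged band-power row per retained epoch.
#'
#' @param rec An [eeg_recording()].
#' @param events Event table, see [extract_epochs()].
#' @param bands Band definitions.
#' @param win_min_s,win_max_s,overlap Welch parameters.
#' @return Tibble with one row per epoch.
#' @export
compute_band_power <- function(rec, events, bands = eeg_bands(),
                               win_min_s = 0.5, win_max_s = 1,
                               overlap = 0.5) {
  eps <- extract_epochs(rec, events, min_duration_s = win_min_s)
  rows <- lapply(eps, epoch_band_row, bands = bands,
                 participant_id = rec$participant_id, run_id = rec$run_id,
                 win_min_s = win_min_s, win_max_s = win_max_s,
                 overlap = overlap)
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- attr(eps, "n_dropped")
  out
}
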