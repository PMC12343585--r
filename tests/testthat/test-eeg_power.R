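make_rec <- function(n = 256 * 60, nch = 2, sfreq = 256, sd = 1, seed = 1) {
  withr::with_seed(seed,
    eeg_recording(matrix(rnorm(nch * n, sd = sd), nch, n), sfreq,
                  participant_id = "p01", run_id = "run01"))
}

test_that("epochs are cut half-open at ROWS/ROWE pairs", {
  rec <- make_rec()
  ev <- tibble::tibble(sample_index = c(100, 612), label = c("ROWS", "ROWE"),
                       unit_id = "u1")
  eps <- extract_epochs(rec, ev)
  expect_length(eps, 1)
  expect_equal(ncol(eps[[1]]$data), 512)
  expect_equal(eps[[1]]$duration_s, 2.0)
  expect_equal(eps[[1]]$data, rec$data[, 101:612])
})

test_that("marker bookkeeping: 20 pairs in, 20 epochs out, ids preserved", {
  rec <- make_rec()
  starts <- seq(0, by = 700, length.out = 20)
  ev <- tibble::tibble(
    sample_index = as.vector(rbind(starts, starts + 512)),
    label = rep(c("ROWS", "ROWE"), 20),
    unit_id = rep(paste0("u", 1:20), each = 2))
  eps <- extract_epochs(rec, ev)
  expect_length(eps, 20)
  expect_equal(vapply(eps, `[[`, character(1), "unit_id"), paste0("u", 1:20))
})

test_that("malformed event tables raise structured errors", {
  rec <- make_rec(n = 5000)
  out_of_order <- tibble::tibble(sample_index = c(200, 100),
                                 label = c("ROWS", "ROWE"), unit_id = "u1")
  expect_error(extract_epochs(rec, out_of_order), "not strictly increasing",
               class = "embedeeg_event_error")
  unmatched <- tibble::tibble(sample_index = c(0, 128, 300),
                              label = c("ROWS", "ROWE", "ROWS"),
                              unit_id = c("u1", "u1", "u2"))
  err <- tryCatch(extract_epochs(rec, unmatched), condition = identity)
  expect_s3_class(err, "embedeeg_event_error")
  expect_match(conditionMessage(err), "u2")
  crossed <- tibble::tibble(sample_index = c(0, 128), label = c("ROWS", "ROWE"),
                            unit_id = c("u1", "u9"))
  expect_error(extract_epochs(rec, crossed), "u1",
               class = "embedeeg_event_error")
})

test_that("epochs too short for the minimum window are dropped and counted", {
  rec <- make_rec(n = 4000)
  ev <- tibble::tibble(sample_index = c(0, 64, 200, 1000),
                       label = rep(c("ROWS", "ROWE"), 2),
                       unit_id = rep(c("short", "long"), each = 2))
  expect_message(eps <- extract_epochs(rec, ev), "1 epoch")
  expect_length(eps, 1)
  expect_equal(attr(eps, "n_dropped"), 1)
  expect_equal(eps[[1]]$unit_id, "long")
})

test_that("Welch PSD recovers sinusoid variance and kills zero signal", {
  sfreq <- 256
  t <- seq(0, 10 - 1 / sfreq, by = 1 / sfreq)
  x <- matrix(2 * sin(2 * pi * 10 * t), 1)
  w <- welch_psd(x, sfreq)
  alpha <- band_power(w$freqs, w$psd)[, "alpha"]
  expect_equal(unname(alpha), 2.0, tolerance = 0.05)   # A^2/2
  expect_true(all(welch_psd(matrix(0, 2, 2560), sfreq)$psd == 0))
  expect_error(welch_psd(matrix(0, 1, 64), 256), "shorter")
})

test_that("Welch PSD is flat at sigma^2/nyquist for white noise", {
  rec <- make_rec(n = 256 * 120, nch = 1, sd = 2, seed = 4)
  w <- welch_psd(rec$data, 256)
  tot <- band_power(w$freqs, w$psd,
                    bands = list(all = c(1, 50)))[, "all"]
  expect_equal(unname(tot), 4 * 49 / 128, tolerance = 0.1)
})

test_that("the Welch window clamps to [win_min, win_max] seconds", {
  sfreq <- 256
  # 0.75 s epoch -> one full-length segment: frequency step 1/0.75 Hz
  w1 <- welch_psd(matrix(rnorm(192), 1), sfreq)
  expect_equal(w1$freqs[2], sfreq / 192)
  # 10 s epoch -> 1 s segments: 1 Hz resolution
  w2 <- welch_psd(matrix(rnorm(2560), 1), sfreq)
  expect_equal(w2$freqs[2], 1)
})

test_that("band integration: rectangles, additivity, Nyquist guard", {
  freqs <- 0:64
  flat <- rep(3, length(freqs))
  bp <- band_power(freqs, flat, bands = list(alpha = c(8, 13)))
  expect_equal(unname(bp[, "alpha"]), 3 * 5)
  # five-band sum equals the 1-50 Hz integral on an edge-aligned grid
  set.seed(5)
  psd <- matrix(rexp(2 * length(freqs)), 2)
  five <- band_power(freqs, psd)
  all50 <- band_power(freqs, psd, bands = list(all = c(1, 50)))
  expect_equal(rowSums(five), all50[, "all"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(band_power(0:32, rep(1, 33), bands = list(g = c(30, 50))),
               "Nyquist")
})

test_that("a narrowband gamma source puts all its power in gamma", {
  ep <- synthesize_eeg(c(delta = 0, theta = 0, alpha = 0, beta = 0,
                         gamma = 1.5), 10, 256, 1, seed = 21)
  w <- welch_psd(ep)
  bp <- band_power(w$freqs, w$psd)
  expect_equal(unname(bp[, "gamma"]), 1.5, tolerance = 0.1)
  expect_true(all(bp[, c("delta", "theta", "alpha")] < 0.02))
})

test_that("channel averaging, ordering and scaling behave physically", {
  sfreq <- 256
  ep1 <- synthesize_eeg(c(delta = .2, theta = .2, alpha = .5, beta = .3,
                          gamma = 1), 4, sfreq, 3, seed = 6)
  row <- epoch_band_row(ep1)
  # mean over channels equals mean of per-channel results
  w <- welch_psd(ep1)
  expect_equal(row$gamma, mean(band_power(w$freqs, w$psd)[, "gamma"]))
  # permuting channels changes nothing
  ep_perm <- ep1; ep_perm$data <- ep1$data[c(3, 1, 2), ]
  expect_equal(epoch_band_row(ep_perm)[, -1], row[, -1])
  # duplicating a channel changes nothing
  ep_dup <- ep1; ep_dup$data <- ep1$data[c(1, 2, 3, 1, 2, 3), ]
  expect_equal(epoch_band_row(ep_dup)[, -1], row[, -1])
  # identical signal on all channels equals the single-channel result
  ep_same <- ep1; ep_same$data <- ep1$data[c(1, 1, 1), ]
  ep_single <- ep1; ep_single$data <- ep1$data[1, , drop = FALSE]
  expect_equal(epoch_band_row(ep_same)[, -1], epoch_band_row(ep_single)[, -1])
  # scaling the signal by c scales every band power by c^2
  ep_sc <- ep1; ep_sc$data <- 3 * ep1$data
  bands <- names(eeg_bands())
  expect_equal(as.numeric(epoch_band_row(ep_sc)[, bands]),
               9 * as.numeric(row[, bands]), tolerance = 1e-9)
})

test_that("two channels with known powers average to their mean", {
  # calibrated channels: gamma variance 1 and 3 -> epoch gamma 2
  e1 <- synthesize_eeg(c(delta = 0, theta = 0, alpha = 0, beta = 0,
                         gamma = 1), 8, 256, 1, seed = 8)
  e2 <- synthesize_eeg(c(delta = 0, theta = 0, alpha = 0, beta = 0,
                         gamma = 3), 8, 256, 1, seed = 9)
  ep <- e1; ep$data <- rbind(e1$data, e2$data)
  w <- welch_psd(ep)
  g <- band_power(w$freqs, w$psd)[, "gamma"]
  expect_equal(mean(g), 2, tolerance = 0.1)
  expect_equal(epoch_band_row(ep)$gamma, mean(g))
})

test_that("compute_band_power yields one calibrated row per epoch", {
  cfg <- sim_config(seed = 3, n_participants = 1, n_runs = 1,
                    n_units_per_run = 5, n_channels = 2,
                    duration_range = c(2, 4))
  tg <- tibble::tibble(unit_id = paste0("u", 1:5),
                       duration_s = c(2, 2.5, 3, 3.5, 4),
                       delta = 4, theta = 3, alpha = 2, beta = 1.5,
                       gamma = 1)
  sr <- synthesize_recording(tg, cfg, participant_id = "p01",
                             run_id = "run01", seed = 11)
  bp <- compute_band_power(sr$recording, sr$events)
  expect_equal(nrow(bp), 5)
  expect_equal(bp$unit_id, tg$unit_id)
  expect_equal(bp$participant_id, rep("p01", 5))
  # short (2-4 s) epochs leave sizable spectral-estimation noise per epoch,
  # especially in the narrow low bands; calibration only holds coarsely here
  for (b in names(eeg_bands()))
    expect_equal(bp[[b]], tg[[b]][seq_len(5)], tolerance = 0.3)
})
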