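#' Simulation configuration
#'
#' Describes a complete synthetic reading study: the crossed design
#' (participants x runs x units), the token-embedding random walks the
#' features are computed from, the linear model tying one band's power to
#' the features, and the signal parameters for realizing those powers as
#' band-limited EEG.
#'
#' Defaults state a desk-scale world: 10 participants x 10 runs x 30
#' units (the crossed structure of a multi-run reading study), units of
#' 4-10 tokens (presentation segments of at most 10 characters),
#' embedding dimension 32 (a computational stand-in for 768-dimensional
#' encoders; all geometry is dimension-generic), per-unit step scales
#' uniform on \[0.5, 1.5\] so cumulative distances vary realistically
#' across units, epoch durations uniform on \[1, 4\] s to exercise the
#' full dynamic Welch-window range, and baseline band powers (arbitrary
#' squared-amplitude units) large enough that the linear power model
#' stays positive.
#'
#' @param seed Master seed; every generator output is a pure function of
#'   (config, seed).
#' @param n_participants,n_runs,n_units_per_run Design sizes.
#' @param d Embedding dimension.
#' @param token_count_range Inclusive integer range of tokens per unit.
#' @param step_scale_range Per-unit adjacent-step scale is drawn
#'   uniformly from this range.
#' @param beta Named numeric vector: effect of each named feature on
#'   `beta_band` (raw feature scale).
#' @param beta_band Band receiving the feature effects; all other bands
#'   are pure noise with respect to the features.
#' @param random_sd Named vector `c(participant, run, residual)` of
#'   random-intercept and residual SDs.
#' @param band_targets Baseline power per band.
#' @param sfreq Sampling rate (Hz) of synthesized EEG.
#' @param n_channels Channels per synthetic recording.
#' @param duration_range Epoch duration range (s).
#' @param gap_s Inter-epoch gap in the continuous recording.
#' @param power_floor Lower floor applied to target powers.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_participants = 10L, n_runs = 10L,
                       n_units_per_run = 30L, d = 32L,
                       token_count_range = c(4L, 10L),
                       step_scale_range = c(0.5, 1.5),
                       beta = c(total_euclidean = 0.12),
                       beta_band = "gamma",
                       random_sd = c(participant = 0.5, run = 0.3,
                                     residual = 0.5),
                       band_targets = c(delta = 20, theta = 15, alpha = 10,
                                        beta = 8, gamma = 12),
                       sfreq = 256, n_channels = 4L,
                       duration_range = c(1, 4), gap_s = 0.125,
                       power_floor = 1e-6) {
  stopifnot(n_participants >= 1L, n_runs >= 1L, n_units_per_run >= 1L,
            d >= 2L, all(random_sd >= 0), all(band_targets > 0),
            beta_band %in% names(band_targets),
            all(names(beta) %in% embedding_feature_names()),
            seed == as.integer(seed), abs(seed) < .Machine$integer.max)
  structure(as.list(environment()), class = "sim_config")
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic expansion of one master seed into independent stage
#' seeds (kept below 2^31), so that a single configured seed governs
#' every source of randomness in a pipeline run.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @param i Optional within-stage index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage, i = 0L) {
  as.integer((as.numeric(seed) * 7919 + .hash32(stage) + 131 * i) %%
               .Machine$integer.max)
}

#' Random-walk token embeddings
#'
#' Generates an n_tokens x d embedding matrix as a Gaussian random walk:
#' `row[i+1] = row[i] + step_scale * g[i]` with independent standard
#' normal steps, starting from a standard normal row.  The expected
#' adjacent Euclidean step is `step_scale * E||g||` (the chi-distribution
#' mean, about `step_scale * sqrt(d)`), so cumulative distances are
#' directly controllable.
#'
#' @param n_tokens Number of rows.
#' @param d Dimension.
#' @param step_scale Step magnitude multiplier (0 gives a constant walk).
#' @param seed Integer seed.
#' @return `embedding_matrix` (see [encode_unit()]) with synthetic
#'   tokens `t1..tn`.
#' @export
gen_embedding_walk <- function(n_tokens, d, step_scale, seed) {
  stopifnot(n_tokens >= 1L, d >= 2L, step_scale >= 0)
  M <- withr::with_seed(as.integer(seed), {
    steps <- matrix(stats::rnorm(n_tokens * d), n_tokens, d)
    steps[-1L, ] <- steps[-1L, , drop = FALSE] * step_scale
    apply(steps, 2L, cumsum)
  })
  if (n_tokens == 1L) M <- matrix(M, nrow = 1L)
  structure(list(unit_id = NA_character_,
                 tokens = paste0("t", seq_len(n_tokens)), M = M,
                 source = "token_encoder"),
            class = "embedding_matrix")
}

# Features plus the walk matrix for one synthetic unit.  The direct
# unit-level encoding is emulated as the token mean plus independent
# noise, so the two norm families correlate without being collinear;
# cumulative surprisal is drawn as a sum of n_tokens Gamma(1, scale=3)
# per-token surprisals (positive, length-coupled).
gen_unit <- function(cfg, seed) {
  withr::with_seed(seed, {
    n_tokens <- sample(seq(cfg$token_count_range[1L],
                           cfg$token_count_range[2L]), 1L)
    step_scale <- stats::runif(1L, cfg$step_scale_range[1L],
                               cfg$step_scale_range[2L])
    wseed <- sample.int(.Machine$integer.max - 1L, 1L)
    v_noise <- stats::rnorm(cfg$d, sd = 0.5)
    surp <- sum(stats::rgamma(n_tokens, shape = 1, scale = 3))
    dur <- stats::runif(1L, cfg$duration_range[1L], cfg$duration_range[2L])
  })
  emb <- gen_embedding_walk(n_tokens, cfg$d, step_scale, wseed)
  v_unit <- colMeans(emb$M) + v_noise
  feats <- c(matrix_unit_features_vec(emb$M, v_unit),
             cumulative_surprisal = surp)
  list(features = feats, emb = emb, v_unit = v_unit, duration_s = dur)
}

#' Generate a feature-coupled band-power analysis table
#'
#' Draws unit features from embedding random walks (so the feature
#' correlation structure is realistic, including the near-collinearity
#' of the Euclidean and Manhattan totals), then builds per-epoch target
#' band powers from the linear mixed model the analysis assumes:
#' `baseline + sum(beta_f * feature_f) + b_participant + b_run + noise`
#' for the configured band, and `baseline + b_participant + b_run +
#' noise` (no feature terms) for every other band.  Targets are floored
#' at `power_floor`.
#'
#' @param cfg A [sim_config()].
#' @return List `(table, truth)`: `table` is one row per
#'   participant x run x unit with ids, duration, the 14 features and
#'   the 5 band-power columns; `truth` holds the per-unit features, the
#'   true beta vector, the drawn random intercepts and the per-epoch
#'   target powers.
#' @export
gen_power_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_units <- cfg$n_runs * cfg$n_units_per_run
  units <- lapply(seq_len(n_units), function(i)
    gen_unit(cfg, derive_seed(cfg$seed, "unit", i)))
  feats <- as.data.frame(do.call(rbind, lapply(units, `[[`, "features")))
  feats$unit_id <- sprintf("r%02d_u%03d",
                           rep(seq_len(cfg$n_runs), each = cfg$n_units_per_run),
                           seq_len(n_units))
  feats$run_id <- sprintf("run%02d",
                          rep(seq_len(cfg$n_runs), each = cfg$n_units_per_run))
  feats$duration_s <- vapply(units, `[[`, numeric(1), "duration_s")

  bands <- names(cfg$band_targets)
  ints <- withr::with_seed(derive_seed(cfg$seed, "intercepts"), list(
    participant = matrix(stats::rnorm(cfg$n_participants * length(bands),
                                      sd = cfg$random_sd[["participant"]]),
                         cfg$n_participants, length(bands),
                         dimnames = list(NULL, bands)),
    run = matrix(stats::rnorm(cfg$n_runs * length(bands),
                              sd = cfg$random_sd[["run"]]),
                 cfg$n_runs, length(bands), dimnames = list(NULL, bands))))

  rows <- vector("list", cfg$n_participants)
  Xbeta <- rep(0, n_units)
  for (f in names(cfg$beta))
    Xbeta <- Xbeta + cfg$beta[[f]] * feats[[f]]
  for (p in seq_len(cfg$n_participants)) {
    eps <- withr::with_seed(derive_seed(cfg$seed, "noise", p),
                            matrix(stats::rnorm(n_units * length(bands),
                                                sd = cfg$random_sd[["residual"]]),
                                   n_units, length(bands)))
    tab <- feats
    tab$participant_id <- sprintf("p%02d", p)
    run_i <- rep(seq_len(cfg$n_runs), each = cfg$n_units_per_run)
    for (j in seq_along(bands)) {
      b <- bands[j]
      mu <- cfg$band_targets[[b]] + ints$participant[p, b] +
        ints$run[run_i, b] + eps[, j]
      if (b == cfg$beta_band) mu <- mu + Xbeta
      tab[[b]] <- pmax(cfg$power_floor, mu)
    }
    rows[[p]] <- tab
  }
  table <- tibble::as_tibble(do.call(rbind, rows))
  front <- c("unit_id", "participant_id", "run_id", "duration_s")
  table <- table[, c(front, setdiff(names(table), front))]
  truth <- list(features = tibble::as_tibble(feats), beta = cfg$beta,
                beta_band = cfg$beta_band, intercepts = ints,
                band_targets = cfg$band_targets,
                target_power = table[, c(front, bands)],
                embeddings = lapply(units, `[[`, "emb"),
                unit_vectors = lapply(units, `[[`, "v_unit"))
  list(table = table, truth = truth)
}

# squared magnitude response of a forward-backward 4th-order Butterworth
# bandpass at frequencies f (Hz)
butter_bp_gain <- function(f, lo, hi, order = 4L) {
  f0sq <- lo * hi
  B <- hi - lo
  x <- ifelse(f > 0, (f^2 - f0sq) / (f * B), Inf)
  1 / (1 + x^(2 * order))
}

#' Synthesize one epoch of band-calibrated EEG
#'
#' Realizes a set of target band powers as multichannel noise: per
#' channel, white Gaussian noise is shaped in the frequency domain with
#' the squared magnitude response of a 4th-order Butterworth bandpass
#' for each band (the steady-state equivalent of forward-backward
#' filtering), each band component is rescaled to exactly its target
#' variance, and the components are summed.  Channels are independent
#' realizations of the same targets, so the channel-averaged band-power
#' pipeline should recover the targets up to spectral-estimation error.
#'
#' @param band_targets Named vector of target powers (variance units),
#'   names matching `bands`.
#' @param duration_s Epoch duration (>= 0.5 s).
#' @param sfreq Sampling rate (Hz).
#' @param n_channels Number of channels.
#' @param seed Integer seed.
#' @param bands Band definition list, default [eeg_bands()].
#' @param unit_id Identifier for the resulting epoch.
#' @return An `eeg_epoch`.
#' @export
synthesize_eeg <- function(band_targets, duration_s, sfreq, n_channels,
                           seed, bands = eeg_bands(),
                           unit_id = NA_character_) {
  stopifnot(duration_s >= 0.5, all(names(bands) %in% names(band_targets)))
  n <- round(duration_s * sfreq)
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * sfreq / n
  gains <- lapply(bands, function(b) butter_bp_gain(abs(f), b[1L], b[2L]))
  X <- withr::with_seed(as.integer(seed),
                        matrix(stats::rnorm(n * n_channels), n, n_channels))
  Z <- stats::mvfft(X)
  out <- matrix(0 + 0i, n, n_channels)
  for (b in names(bands)) {
    W <- Z * gains[[b]]
    v <- colSums(Mod(W)^2) / n^2          # population variance per channel
    tgt <- max(band_targets[[b]], 0)
    alpha <- ifelse(v > 0, sqrt(tgt / v), 0)
    out <- out + sweep(W, 2L, alpha, `*`)
  }
  data <- t(Re(stats::mvfft(out, inverse = TRUE) / n))
  structure(list(unit_id = unit_id, data = data, sfreq = sfreq,
                 duration_s = n / sfreq),
            class = "eeg_epoch")
}

#' Synthesize a continuous recording with event markers
#'
#' Concatenates per-epoch synthetic signals with silent inter-epoch gaps
#' and emits the matching ROWS/ROWE event table (0-based sample indices,
#' half-open epochs), ready for [extract_epochs()].
#'
#' @param epoch_targets Data frame with columns `unit_id`, `duration_s`
#'   and one column per band (target powers).
#' @param cfg A [sim_config()] (supplies sfreq, channel count, gap).
#' @param participant_id,run_id Stamped on the recording.
#' @param seed Integer seed.
#' @param bands Band definitions.
#' @return List `(recording, events)`.
#' @export
synthesize_recording <- function(epoch_targets, cfg,
                                 participant_id = NA_character_,
                                 run_id = NA_character_,
                                 seed = cfg$seed, bands = eeg_bands()) {
  stopifnot(inherits(cfg, "sim_config"))
  gap <- round(cfg$gap_s * cfg$sfreq)
  segs <- vector("list", nrow(epoch_targets))
  ev <- vector("list", nrow(epoch_targets))
  pos <- gap                               # 0-based cursor
  for (i in seq_len(nrow(epoch_targets))) {
    tg <- unlist(epoch_targets[i, names(bands)])
    ep <- synthesize_eeg(tg, epoch_targets$duration_s[i], cfg$sfreq,
                         cfg$n_channels, derive_seed(seed, "epoch", i),
                         bands = bands, unit_id = epoch_targets$unit_id[i])
    n <- ncol(ep$data)
    segs[[i]] <- ep$data
    ev[[i]] <- tibble::tibble(
      sample_index = c(pos, pos + n), label = c("ROWS", "ROWE"),
      unit_id = as.character(epoch_targets$unit_id[i]))
    pos <- pos + n + gap
  }
  nch <- cfg$n_channels
  data <- matrix(0, nch, pos)
  for (i in seq_along(segs)) {
    s0 <- ev[[i]]$sample_index[1L]
    data[, (s0 + 1L):(s0 + ncol(segs[[i]]))] <- segs[[i]]
  }
  list(recording = eeg_recording(data, cfg$sfreq,
                                 participant_id = participant_id,
                                 run_id = run_id),
       events = do.call(rbind, ev))
}

#' Simulate a full dataset on disk
#'
#' Writes everything the pipeline consumes: a units TSV, an embedding
#' archive (.rds; per-unit walk matrices, unit vectors and simulated
#' surprisal), the ground-truth feature CSV, one recording archive plus
#' events TSV per participant x run, and a ground-truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the `gen_power_table()` result plus the file
#'   manifest.
#' @export
simulate_eeg_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- gen_power_table(cfg)
  feats <- gp$truth$features
  units <- tibble::tibble(unit_id = feats$unit_id, material = "simulated",
                          run_id = feats$run_id,
                          text = vapply(gp$truth$embeddings, function(e)
                            paste(e$tokens, collapse = " "), character(1)))
  readr::write_tsv(units, file.path(dir, "units.tsv"))
  archive <- stats::setNames(lapply(seq_len(nrow(feats)), function(i)
    list(M = gp$truth$embeddings[[i]]$M,
         v_unit = gp$truth$unit_vectors[[i]],
         cumulative_surprisal = feats$cumulative_surprisal[i])),
    feats$unit_id)
  saveRDS(archive, file.path(dir, "embeddings.rds"))
  write_features_csv(feature_table(feats), file.path(dir, "features.csv"))

  bands <- names(cfg$band_targets)
  recs <- character(0)
  for (p in sprintf("p%02d", seq_len(cfg$n_participants))) {
    for (r in sprintf("run%02d", seq_len(cfg$n_runs))) {
      sel <- gp$table$participant_id == p & gp$table$run_id == r
      tg <- gp$table[sel, c("unit_id", "duration_s", bands)]
      sr <- synthesize_recording(tg, cfg, participant_id = p, run_id = r,
                                 seed = derive_seed(cfg$seed, paste0(p, r)))
      stem <- file.path(dir, sprintf("eeg_%s_%s", p, r))
      saveRDS(sr$recording, paste0(stem, ".rds"))
      readr::write_tsv(sr$events, paste0(stem, "_events.tsv"))
      recs <- c(recs, stem)
    }
  }
  jsonlite::write_json(
    list(seed = cfg$seed, beta = as.list(cfg$beta),
         beta_band = cfg$beta_band,
         band_targets = as.list(cfg$band_targets),
         random_sd = as.list(cfg$random_sd)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(sim = gp, recordings = recs, dir = dir))
}

# canonical features-CSV column selection/order
feature_table <- function(feats) {
  feats[, c("unit_id", "n_tokens", embedding_feature_names())]
}
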