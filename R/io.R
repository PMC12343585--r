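#' Read reading-unit and event tables
#'
#' Units are UTF-8 TSV with at least `unit_id` and `text` (optionally
#' `material`, `run_id`, `participant_id`); events are TSV with
#' `sample_index` (0-based integer), `label` (ROWS/ROWE) and `unit_id`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_units <- function(path) {
  if (!file.exists(path)) stop("read_units: file not found: ", path,
                               call. = FALSE)
  u <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("unit_id", "text") %in% names(u)))
    stop("read_units: columns unit_id and text are required", call. = FALSE)
  u
}

#' @rdname read_units
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("read_events: file not found: ", path,
                               call. = FALSE)
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_index", "label", "unit_id") %in% names(ev)))
    stop("read_events: columns sample_index, label, unit_id are required",
         call. = FALSE)
  ev
}

#' Read an EEG recording from EDF or an array archive
#'
#' `.edf` files go through [read_edf()]; anything else is treated as an
#' `.rds` archive holding an [eeg_recording()] (the format written by
#' [write_recording()] and the simulator).  Channels listed in
#' `excluded_channels` are dropped after load.
#'
#' @param path File path.
#' @param excluded_channels Channel names to drop (config-driven).
#' @param participant_id,run_id Identifiers (override the archive's).
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, excluded_channels = NULL,
                     participant_id = NULL, run_id = NULL) {
  if (!file.exists(path))
    stop("read_eeg: file not found: ", path, call. = FALSE)
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path)
  } else {
    obj <- readRDS(path)
    if (!inherits(obj, "eeg_recording"))
      stop("read_eeg: ", path, " does not contain an eeg_recording",
           call. = FALSE)
    # revalidate, e.g. duplicate channels or bad sfreq in a foreign archive
    eeg_recording(obj$data, obj$sfreq, obj$channel_names,
                  obj$participant_id, obj$run_id)
  }
  if (!is.null(participant_id)) rec$participant_id <- participant_id
  if (!is.null(run_id)) rec$run_id <- run_id
  if (length(excluded_channels)) rec <- exclude_channels(rec, excluded_channels)
  rec
}

#' @rdname read_eeg
#' @param rec Recording to save.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' Write/read the canonical CSV outputs
#'
#' All outputs are UTF-8 CSV with '.' as decimal separator and a header,
#' written with deterministic row and column order so identical inputs
#' produce byte-identical files.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(x, path) {
  cols <- c("unit_id", "n_tokens", embedding_feature_names())
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(x[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
write_band_power_csv <- function(x, path) {
  cols <- c("unit_id", "participant_id", "run_id", "duration_s",
            names(eeg_bands()))
  stopifnot(all(cols %in% names(x)))
  readr::write_csv(x[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @param set A `band_lmm_set` from [run_full_analysis()].
#' @param dir Output directory.
#' @export
write_results <- function(set, dir) {
  stopifnot(inherits(set, "band_lmm_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(set$results, file.path(dir, "lmm_results.csv"),
                   progress = FALSE)
  readr::write_csv(set$varcomp, file.path(dir, "variance_components.csv"),
                   progress = FALSE)
  cm <- tibble::tibble(feature = rownames(set$feature_correlations),
                       tibble::as_tibble(set$feature_correlations))
  readr::write_csv(cm, file.path(dir, "feature_correlations.csv"),
                   progress = FALSE)
  invisible(dir)
}

# default pipeline configuration; unknown user keys are rejected
default_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    simulate = NULL,          # list of sim_config() overrides, or NULL
    paths = list(eeg = NULL, events = NULL, units = NULL,
                 embeddings = NULL, features = NULL, power = NULL),
    eeg_power = list(win_min_s = 0.5, win_max_s = 1, overlap = 0.5,
                     excluded_channels = character(0)),
    features = list(d = 768L, encoder = "hash", encoder_seed = 1L,
                    tokenizer = "chars"),
    surprisal = list(base = "e", p_floor = 1e-12, lm = "none"),
    stats = list(bands = c("delta", "theta", "alpha", "beta", "gamma"),
                 outlier_k = 2.5, interactions = FALSE,
                 bh_correct = FALSE, log_power = FALSE,
                 standardize = FALSE)
  )
}

#' Read a pipeline configuration
#'
#' JSON with the keys of the default configuration; unknown keys at the
#' top level or within a section are rejected so typos fail loudly.
#'
#' @param path Path to a JSON config.
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: file not found: ", path,
                               call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(def[[k]]))
      if (length(bad) && k != "simulate")
        stop("read_config: unknown key(s) in '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      def[[k]][names(user[[k]])] <- user[[k]]
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}
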