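#' Exclude extreme rows by the k-standard-deviation rule
#'
#' Screens each listed column once against the mean and sample SD of the
#' *full* table (not iteratively): a row is dropped when any screened
#' value deviates from its column mean by more than `k` SDs.  The default
#' k = 2.5 is the screening criterion applied before model fitting.
#' Zero-variance columns cannot produce outliers and are skipped with a
#' warning.  The rule is order-independent: shuffling rows changes
#' nothing but row order of the result.
#'
#' @param data Data frame.
#' @param columns Character vector of columns to screen.
#' @param k Cutoff in SDs (> 0; `Inf` disables screening).
#' @return List `(data, n_excluded)`.
#' @export
exclude_outliers <- function(data, columns, k = 2.5) {
  stopifnot(is.data.frame(data), k > 0)
  columns <- intersect(columns, names(data))
  drop <- rep(FALSE, nrow(data))
  for (cl in columns) {
    x <- data[[cl]]
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("exclude_outliers: column '", cl,
              "' has zero variance; skipped", call. = FALSE)
      next
    }
    drop <- drop | abs(x - m) > k * s
  }
  list(data = data[!drop, , drop = FALSE], n_excluded = sum(drop))
}

#' Fit one band-power linear mixed model
#'
#' The statistical core of the pipeline: for one frequency band,
#' \deqn{power = \beta_0 + \sum_f \beta_f \cdot feature_f
#'       + b_{participant} + b_{run} + \varepsilon,}
#' with crossed random intercepts for participant and run, fitted by
#' REML.  Inference per fixed effect is Wald: `z = beta/SE` and
#' `p = 2 * pnorm(-|z|)` (two-sided normal tail).  The feature set is
#' deliberately entered on raw scales and in full — no term is removed
#' for insignificance — so collinearity diagnostics (design-matrix
#' condition number and the largest absolute pairwise feature
#' correlation) are attached to every result.
#'
#' @param data Analysis table (already screened for outliers).
#' @param response Name of the band-power column.
#' @param features Fixed-effect column names (default the 14 features).
#' @param participant_col,run_col Grouping-factor columns.
#' @param extra_fixed Additional fixed-effect terms (e.g. `material` or
#'   interaction terms) appended verbatim to the formula.
#' @return Object of class `lmm_result`: tibble `coefficients`
#'   (term, beta, se, z, p), tibble `varcomp` (participant, run and
#'   residual variances), `n_obs`, `diagnostics`, and the fitted
#'   `lme4` model in `$model`.
#' @export
fit_band_lmm <- function(data, response,
                         features = embedding_feature_names(),
                         participant_col = "participant_id",
                         run_col = "run_id", extra_fixed = character(0)) {
  stopifnot(is.data.frame(data),
            response %in% names(data),
            all(features %in% names(data)),
            participant_col %in% names(data), run_col %in% names(data))
  if (length(unique(data[[participant_col]])) < 2L ||
      length(unique(data[[run_col]])) < 2L)
    stop("fit_band_lmm: need at least 2 participants and 2 runs",
         call. = FALSE)
  fixed_terms <- c(features, extra_fixed)
  if (!length(fixed_terms)) stop("fit_band_lmm: empty feature set",
                                 call. = FALSE)
  mm <- stats::model.matrix(stats::reformulate(fixed_terms), data)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrx$pivot[(qrx$rank + 1L):ncol(mm)]]
    stop("fit_band_lmm: design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(
    c(fixed_terms,
      sprintf("(1 | %s)", participant_col), sprintf("(1 | %s)", run_col)),
    response = response)
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("fit_band_lmm: optimizer did not converge (code ",
         fit@optinfo$conv$opt, "); trace: ",
         paste(deparse(fit@optinfo$message), collapse = " "), call. = FALSE)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(
    group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
  Xf <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  cm <- if (ncol(Xf) >= 2L) stats::cor(Xf) else matrix(1, 1, 1)
  off <- if (ncol(Xf) >= 2L) abs(cm[upper.tri(cm)]) else 0
  structure(list(
    response = response,
    coefficients = tibble::tibble(term = names(beta), beta = unname(beta),
                                  se = unname(se), z = unname(z),
                                  p = unname(p)),
    varcomp = varcomp,
    n_obs = nrow(data),
    n_excluded = NA_integer_,
    diagnostics = list(kappa = kappa(mm, exact = FALSE),
                       max_abs_corr = max(off)),
    model = fit), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model for band '", x$response, "' (REML, crossed ",
      "random intercepts)\n", sep = "")
  cat("  n_obs:", x$n_obs, " max |feature corr|:",
      format(x$diagnostics$max_abs_corr, digits = 4), "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Run the full feature-to-band-power analysis
#'
#' Joins the per-unit feature table to the per-epoch band-power table,
#' screens extreme values (response and all features, per model, k SDs),
#' and fits one mixed model per band.  Significance is flagged at
#' alpha = 0.05 with an additional reporting tier at p < 0.1 (strict
#' inequalities).  No multiple-comparison correction is applied by
#' default; `bh_correct = TRUE` adds Benjamini-Hochberg adjusted
#' p-values per band as an extra column.
#'
#' With `interactions = TRUE` and at least two levels in `material_col`,
#' each band is additionally fitted with material and material-by-feature
#' interaction terms (the combined-materials analysis); the plain model
#' is retained as the reduced model.
#'
#' @param features Feature table (one row per unit, the 14 feature
#'   columns plus `unit_id`).
#' @param power Band-power table (one row per participant x run x unit).
#' @param bands Band (response) names to model.
#' @param feature_cols Fixed-effect columns.
#' @param outlier_k SD cutoff for the screening rule.
#' @param interactions Fit material x feature interactions.
#' @param material_col Material column name in `features`.
#' @param bh_correct Add BH-adjusted p-values (off by default).
#' @param log_power Model `log(power)` instead of raw power.
#' @param standardize Z-score the features before fitting (off: raw
#'   scales).
#' @return Object of class `band_lmm_set`: `results` (tibble over all
#'   bands: band, feature, beta, se, z, p, sig_05, sig_10), `varcomp`,
#'   `feature_correlations` (the features' correlation matrix on the
#'   analysis table), `models` (named list of `lmm_result`), and
#'   `n_excluded` per band.
#' @export
run_full_analysis <- function(features, power, bands = names(eeg_bands()),
                              feature_cols = embedding_feature_names(),
                              outlier_k = 2.5, interactions = FALSE,
                              material_col = "material",
                              bh_correct = FALSE, log_power = FALSE,
                              standardize = FALSE) {
  stopifnot(is.data.frame(features), is.data.frame(power))
  if (!length(feature_cols)) stop("run_full_analysis: empty feature set",
                                  call. = FALSE)
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols))
    stop("run_full_analysis: feature column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  orphans_p <- setdiff(power$unit_id, features$unit_id)
  orphans_f <- setdiff(features$unit_id, power$unit_id)
  if (length(orphans_p))
    stop("run_full_analysis: band-power rows with no matching feature ",
         "row; orphaned unit_id(s): ",
         paste(utils::head(orphans_p, 10L), collapse = ", "), call. = FALSE)
  if (length(orphans_f))
    warning("run_full_analysis: ", length(orphans_f),
            " feature row(s) without band-power rows are ignored",
            call. = FALSE)
  keep <- unique(c("unit_id", material_col, feature_cols))
  keep <- intersect(keep, names(features))
  tab <- merge(power, features[, keep], by = "unit_id", sort = FALSE)
  if (anyNA(tab[, c(feature_cols, bands)]))
    stop("run_full_analysis: missing values in analysis table after join",
         call. = FALSE)
  if (log_power) for (b in bands) tab[[b]] <- log(tab[[b]])
  if (standardize) for (f in feature_cols) tab[[f]] <- as.numeric(scale(tab[[f]]))
  tab <- tab[order(tab$participant_id, tab$run_id, tab$unit_id), ,
             drop = FALSE]

  with_material <- interactions && material_col %in% names(tab) &&
    length(unique(tab[[material_col]])) >= 2L
  extra <- if (with_material)
    c(material_col, paste0(material_col, ":", feature_cols)) else character(0)

  models <- list()
  res_rows <- list()
  vc_rows <- list()
  nexc <- integer(0)
  for (b in bands) {
    scr <- exclude_outliers(tab, c(b, feature_cols), k = outlier_k)
    fit <- fit_band_lmm(scr$data, response = b, features = feature_cols,
                        extra_fixed = extra)
    fit$n_excluded <- scr$n_excluded
    if (with_material) {
      reduced <- fit_band_lmm(scr$data, response = b,
                              features = feature_cols)
      reduced$n_excluded <- scr$n_excluded
      models[[paste0(b, "_reduced")]] <- reduced
    }
    models[[b]] <- fit
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    co$sig_05 <- co$p < 0.05
    co$sig_10 <- co$p < 0.1
    if (bh_correct) co$p_bh <- stats::p.adjust(co$p, method = "BH")
    res_rows[[b]] <- tibble::tibble(band = b, co)
    vc_rows[[b]] <- tibble::tibble(band = b, fit$varcomp)
    nexc[b] <- scr$n_excluded
  }
  results <- do.call(rbind, res_rows)
  names(results)[names(results) == "term"] <- "feature"
  structure(list(results = results,
                 varcomp = do.call(rbind, vc_rows),
                 feature_correlations = stats::cor(as.matrix(
                   tab[, feature_cols, drop = FALSE])),
                 models = models,
                 n_excluded = nexc,
                 table = tibble::as_tibble(tab)),
            class = "band_lmm_set")
}

#' @export
print.band_lmm_set <- function(x, ...) {
  cat("Band-power mixed-model set:", length(unique(x$results$band)),
      "band(s),", nrow(x$table), "observations\n")
  sig <- x$results[x$results$sig_05, c("band", "feature", "beta", "se",
                                       "z", "p")]
  if (nrow(sig)) {
    cat("Fixed effects with p < 0.05:\n"); print(sig, n = Inf)
  } else cat("No fixed effect reached p < 0.05.\n")
  invisible(x)
}
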