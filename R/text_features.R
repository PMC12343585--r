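#' Cumulative distance along a token-embedding trajectory
#'
#' The central text metric of the pipeline: the sum of a vector distance
#' over consecutive token pairs within a unit,
#' \deqn{\sum_{i=1}^{n-1} dist(x_i, x_{i+1}).}
#' A large cumulative Euclidean distance means large sequential shifts in
#' meaning between adjacent tokens; cosine distance
#' (\eqn{1 - \cos\theta}, range \[0, 2\]) isolates directional change and
#' ignores magnitude; Manhattan and Chebyshev are the L1 and L-infinity
#' counterparts.
#'
#' @param M Numeric matrix (n_tokens x d) or an `embedding_matrix`.
#' @param metric One of `"euclidean"`, `"cosine"`, `"manhattan"`,
#'   `"chebyshev"`.
#' @return Nonnegative scalar; 0 when the unit has a single token.
#' @export
cumulative_distance <- function(M,
                                metric = c("euclidean", "cosine",
                                           "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  M <- embedding_rows(M)
  n <- nrow(M)
  if (n < 2L) return(0)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0))
      stop("cumulative_distance: zero-norm embedding row; cosine distance ",
           "is undefined for row(s) ", paste(which(nrm == 0), collapse = ", "),
           call. = FALSE)
    dots <- rowSums(M[-n, , drop = FALSE] * M[-1L, , drop = FALSE])
    cosines <- dots / (nrm[-n] * nrm[-1L])
    # clamp rounding excursions outside [-1, 1]
    return(sum(1 - pmin(1, pmax(-1, cosines))))
  }
  D <- M[-1L, , drop = FALSE] - M[-n, , drop = FALSE]
  switch(metric,
    euclidean = sum(sqrt(rowSums(D^2))),
    manhattan = sum(abs(D)),
    chebyshev = sum(apply(abs(D), 1L, max))
  )
}

embedding_rows <- function(M) {
  if (inherits(M, "embedding_matrix")) M <- M$M
  M <- as.matrix(M)
  stopifnot(is.numeric(M), ncol(M) >= 1L, all(is.finite(M)))
  M
}

#' Mean-of-token unit vector
#'
#' Collapses an n_tokens x d embedding matrix to a single d-vector by
#' averaging over tokens (the column-wise mean), the standard pooled
#' sentence representation when no dedicated sentence encoder is used.
#'
#' @inheritParams cumulative_distance
#' @return Numeric d-vector with attribute `provenance = "mean_of_tokens"`.
#' @export
unit_vector_from_tokens <- function(M) {
  M <- embedding_rows(M)
  structure(colMeans(M), provenance = "mean_of_tokens")
}

#' Vector norms of a unit embedding
#'
#' @param v Numeric vector.
#' @return Named numeric vector `c(euclid, manhattan, chebyshev)` — the
#'   L2, L1 and L-infinity norms.  `chebyshev <= euclid <= manhattan`
#'   always holds.
#' @export
vector_norms <- function(v) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  c(euclid = sqrt(sum(v^2)), manhattan = sum(abs(v)),
    chebyshev = max(abs(v)))
}

#' Project token embeddings onto their top-2 principal components
#'
#' Centers the unit's own token matrix and projects it onto its first two
#' right singular vectors (per-unit PCA).  The projection is the canvas
#' for the convex-hull features: each token becomes a point in the plane.
#' If fewer than 3 tokens are present, or the centered matrix has rank
#' below 2, the missing component(s) are zero-filled and the result is
#' flagged degenerate.
#'
#' @inheritParams cumulative_distance
#' @return List of class `projection_2d`: `P` (n_tokens x 2),
#'   `explained_variance` (length 2), `degenerate` (logical).
#' @export
project_2d <- function(M) {
  M <- embedding_rows(M)
  n <- nrow(M)
  C <- sweep(M, 2L, colMeans(M))
  P <- matrix(0, n, 2L)
  ev <- c(0, 0)
  rank2 <- FALSE
  if (n >= 2L) {
    s <- svd(C, nu = 2L, nv = 0L)
    tol <- max(dim(C)) * .Machine$double.eps * s$d[1L]
    r <- sum(s$d > max(tol, 0))
    k <- min(2L, r)
    if (k > 0L)
      P[, seq_len(k)] <- s$u[, seq_len(k), drop = FALSE] %*%
        diag(s$d[seq_len(k)], k, k)
    ev[seq_len(min(2L, length(s$d)))] <-
      s$d[seq_len(min(2L, length(s$d)))]^2 / max(1L, n - 1L)
    rank2 <- r >= 2L
  }
  structure(list(P = P, explained_variance = ev,
                 degenerate = !(n >= 3L && rank2)),
            class = "projection_2d")
}

#' Convex-hull geometry of projected tokens
#'
#' From the 2-D projected token points, computes three spread summaries:
#' * `neighbor_sum` — sum of Euclidean distances between consecutive
#'   tokens *in reading order* within the plane (the projected trajectory
#'   length; deliberately distinct from the hull perimeter);
#' * `perimeter` — perimeter of the convex hull of all points;
#' * `area` — its enclosed area (shoelace formula).
#'
#' Degenerate cases: a single (or fully coincident) point set gives
#' (0, 0, 0); two distinct points give (d, 2d, 0); collinear points give
#' area 0 and perimeter twice the largest pairwise distance.
#'
#' @param P A `projection_2d` or an n x 2 numeric matrix.
#' @return Named numeric vector `c(neighbor_sum, perimeter, area)`.
#' @export
hull_features <- function(P) {
  if (inherits(P, "projection_2d")) P <- P$P
  P <- as.matrix(P)
  stopifnot(ncol(P) == 2L, all(is.finite(P)))
  n <- nrow(P)
  if (n == 1L)
    return(c(neighbor_sum = 0, perimeter = 0, area = 0))
  steps <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  neighbor_sum <- sum(steps)
  h <- grDevices::chull(P[, 1L], P[, 2L])
  H <- P[h, , drop = FALSE]
  m <- nrow(H)
  if (m == 1L) {
    perimeter <- 0; area <- 0
  } else if (m == 2L) {
    perimeter <- 2 * sqrt(sum((H[1L, ] - H[2L, ])^2))
    area <- 0
  } else {
    nxt <- c(2:m, 1L)
    edges <- sqrt(rowSums((H[nxt, , drop = FALSE] - H)^2))
    perimeter <- sum(edges)
    area <- abs(sum(H[, 1L] * H[nxt, 2L] - H[nxt, 1L] * H[, 2L])) / 2
  }
  c(neighbor_sum = neighbor_sum, perimeter = perimeter, area = area)
}

#' Names of the fourteen model features
#'
#' The fixed-effect columns used in the band-power mixed models, in
#' canonical order: four cumulative distances, three norms of the
#' mean-of-token vector, three norms of the direct unit encoding,
#' three hull-geometry features, and cumulative surprisal.
#'
#' @return Character vector of length 14.
#' @export
embedding_feature_names <- function() {
  c("total_euclidean", "total_cosine", "total_manhattan", "total_chebyshev",
    "norm_euclid_tok", "norm_manhattan_tok", "norm_chebyshev_tok",
    "norm_euclid_unit", "norm_manhattan_unit", "norm_chebyshev_unit",
    "hull_neighbor_sum", "hull_perimeter", "hull_area",
    "cumulative_surprisal")
}

# Geometry features from a ready-made embedding matrix plus a unit-level
# vector; shared by the encoder path and the synthetic generator.  The
# vector form avoids per-unit tibble construction in tight loops.
matrix_unit_features_vec <- function(M, v_unit) {
  v_tok <- unit_vector_from_tokens(M)
  nt <- vector_norms(v_tok)
  nu <- vector_norms(v_unit)
  hull <- hull_features(project_2d(M))
  c(n_tokens = nrow(embedding_rows(M)),
    total_euclidean = cumulative_distance(M, "euclidean"),
    total_cosine = cumulative_distance(M, "cosine"),
    total_manhattan = cumulative_distance(M, "manhattan"),
    total_chebyshev = cumulative_distance(M, "chebyshev"),
    norm_euclid_tok = nt[["euclid"]],
    norm_manhattan_tok = nt[["manhattan"]],
    norm_chebyshev_tok = nt[["chebyshev"]],
    norm_euclid_unit = nu[["euclid"]],
    norm_manhattan_unit = nu[["manhattan"]],
    norm_chebyshev_unit = nu[["chebyshev"]],
    hull_neighbor_sum = hull[["neighbor_sum"]],
    hull_perimeter = hull[["perimeter"]],
    hull_area = hull[["area"]])
}

matrix_unit_features <- function(M, v_unit) {
  tibble::as_tibble(as.list(matrix_unit_features_vec(M, v_unit)))
}

#' Compute the per-unit feature row
#'
#' Runs the full geometry stack for one unit: encode tokens, sum the four
#' adjacent-pair distances, take norms of the mean-of-token vector and of
#' the direct unit encoding, project to 2-D and measure the hull.  The
#' `cumulative_surprisal` column is filled only when a masked language
#' model is supplied (see [cumulative_surprisal()]); otherwise it is `NA`
#' so the surprisal stage can complete it later.
#'
#' @param text Unit text.
#' @param token_encoder A [token_encoder()].
#' @param unit_encoder A [unit_encoder()].
#' @param masked_lm Optional [masked_lm()] for surprisal.
#' @param unit_id Identifier carried into the output row.
#' @param ... Passed to [cumulative_surprisal()] (e.g. `base`, `p_floor`).
#' @return One-row tibble with columns `unit_id`, `n_tokens` and the 14
#'   features of [embedding_feature_names()].
#' @export
compute_unit_features <- function(text, token_encoder, unit_encoder,
                                  masked_lm = NULL,
                                  unit_id = NA_character_, ...) {
  emb <- encode_unit(text, token_encoder, unit_id = unit_id)
  v_unit <- unit_encoder$encode(text)
  stopifnot(is.numeric(v_unit), all(is.finite(v_unit)))
  row <- matrix_unit_features(emb$M, v_unit)
  surp <- if (is.null(masked_lm)) NA_real_ else
    cumulative_surprisal(emb$tokens, masked_lm, ...)$cumulative
  tibble::tibble(unit_id = unit_id, row, cumulative_surprisal = surp)
}

#' Compute features for a table of units
#'
#' @param units Data frame with columns `unit_id` and `text` (extra
#'   columns such as `material` or `run_id` are carried through untouched).
#' @inheritParams compute_unit_features
#' @return Tibble with one row per unit; errors in any sub-operation are
#'   re-raised with the offending `unit_id` attached.
#' @export
compute_features <- function(units, token_encoder, unit_encoder,
                             masked_lm = NULL, ...) {
  stopifnot(is.data.frame(units), all(c("unit_id", "text") %in% names(units)))
  rows <- lapply(seq_len(nrow(units)), function(i) {
    tryCatch(
      compute_unit_features(units$text[i], token_encoder, unit_encoder,
                            masked_lm = masked_lm,
                            unit_id = as.character(units$unit_id[i]), ...),
      error = function(e)
        stop("feature computation failed for unit_id=", units$unit_id[i],
             ": ", conditionMessage(e), call. = FALSE))
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(units), c("unit_id", "text", names(out)))
  for (cl in extra) out[[cl]] <- units[[cl]]
  out
}
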