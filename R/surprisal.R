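#' Masked language-model interface
#'
#' Surprisal is computed by the mask-one-position-at-a-time procedure:
#' for each token position the model sees the unit with that single token
#' replaced by a mask, and returns its probability distribution over the
#' vocabulary at the masked slot.  The interface is deliberately minimal
#' so that real pretrained models can be plugged in, while tests run on
#' deterministic mocks:
#' * `predict(tokens, i)` — numeric vector of length `vocab_size`,
#'   nonnegative, summing to 1 (checked to 1e-6);
#' * `vocab_index(token)` — 1-based index of a token string in the
#'   vocabulary.
#'
#' @param predict,vocab_index Functions as described above.
#' @param vocab_size Integer vocabulary size V.
#' @param name Tag for printing.
#' @return Object of class `masked_lm`.
#' @export
masked_lm <- function(predict, vocab_index, vocab_size, name = "custom") {
  stopifnot(is.function(predict), is.function(vocab_index),
            is.numeric(vocab_size), vocab_size >= 1)
  structure(list(predict = predict, vocab_index = vocab_index,
                 vocab_size = as.integer(vocab_size), name = name),
            class = "masked_lm")
}

#' Mock masked language models
#'
#' Three deterministic stand-ins used throughout the test suite:
#' * `mock_lm_uniform(V)` — every token gets probability 1/V, so each
#'   masked position contributes exactly `log(V)` nats;
#' * `mock_lm_oracle()` — probability 1 on the true token (surprisal 0);
#' * `mock_lm_seeded(V, seed)` — a reproducible pseudo-random
#'   distribution per (context, position), for determinism tests.
#'
#' @param V Vocabulary size.
#' @param seed Integer seed mixed into the per-position hash.
#' @return A [masked_lm()].
#' @export
mock_lm_uniform <- function(V = 100L) {
  V <- as.integer(V)
  masked_lm(
    predict = function(tokens, i) rep(1 / V, V),
    vocab_index = function(token) (.hash32(token) %% V) + 1L,
    vocab_size = V, name = sprintf("uniform(V=%d)", V))
}

#' @rdname mock_lm_uniform
#' @export
mock_lm_oracle <- function(V = 100L) {
  V <- as.integer(V)
  idx <- function(token) (.hash32(token) %% V) + 1L
  masked_lm(
    predict = function(tokens, i) {
      p <- numeric(V); p[idx(tokens[i])] <- 1; p
    },
    vocab_index = idx, vocab_size = V, name = "oracle")
}

#' @rdname mock_lm_uniform
#' @export
mock_lm_seeded <- function(V = 100L, seed = 1L) {
  V <- as.integer(V)
  masked_lm(
    predict = function(tokens, i) {
      h <- (.hash32(paste(c(tokens, "@", i), collapse = "\x01")) + seed) %%
        .Machine$integer.max
      p <- withr::with_seed(h, stats::rexp(V))
      p / sum(p)
    },
    vocab_index = function(token) (.hash32(token) %% V) + 1L,
    vocab_size = V, name = sprintf("seeded(V=%d,seed=%d)", V, seed))
}

#' Surprisal of one token under a masked LM
#'
#' Masks position `i`, reads the model's probability for the token that
#' is actually there, and returns \eqn{-\log p} (nats by default).  The
#' probability is floored at `p_floor` before the log so degenerate mock
#' models cannot produce infinities.
#'
#' @param tokens Character vector of unit tokens (no special markers).
#' @param i Position to mask, `1 <= i <= length(tokens)`.
#' @param lm A [masked_lm()].
#' @param base Logarithm base; `exp(1)` for nats (default), 2 for bits.
#' @param p_floor Probability floor (default 1e-12).
#' @return List `(probability, surprisal)`.
#' @export
token_surprisal <- function(tokens, i, lm, base = exp(1), p_floor = 1e-12) {
  stopifnot(inherits(lm, "masked_lm"), i >= 1L, i <= length(tokens))
  p <- lm$predict(tokens, i)
  if (length(p) != lm$vocab_size || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("masked_lm contract violated: predict() must return a ",
         "nonnegative length-V distribution summing to 1 (got sum=",
         format(sum(p)), ")", call. = FALSE)
  pi <- p[lm$vocab_index(tokens[i])]
  list(probability = pi,
       surprisal = -log(max(pi, p_floor)) / log(base))
}

#' Cumulative surprisal of a unit
#'
#' Applies [token_surprisal()] to every position in turn — exactly
#' `length(tokens)` single-mask model evaluations — and sums the
#' per-token values into the unit-level unpredictability score used as
#' the fourteenth model feature.
#'
#' @inheritParams token_surprisal
#' @return List of class `surprisal_result`: `per_token` (tibble with
#'   position, token, probability, surprisal) and `cumulative`.
#' @export
cumulative_surprisal <- function(tokens, lm, base = exp(1), p_floor = 1e-12) {
  stopifnot(length(tokens) >= 1L)
  rows <- lapply(seq_along(tokens), function(i) {
    ts <- token_surprisal(tokens, i, lm, base = base, p_floor = p_floor)
    tibble::tibble(position = i, token = tokens[i],
                   probability = ts$probability, surprisal = ts$surprisal)
  })
  per_token <- do.call(rbind, rows)
  structure(list(per_token = per_token,
                 cumulative = sum(per_token$surprisal)),
            class = "surprisal_result")
}
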