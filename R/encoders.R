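#' Tokenizers
#'
#' `tokenize_chars()` splits text into single characters (the natural unit
#' for logographic scripts, where language models emit one token per
#' character); `tokenize_words()` splits on whitespace (a stand-in for
#' word/subword tokenization of alphabetic text).  Whitespace itself is
#' never a token.
#'
#' @param text A length-1 character string.
#' @return Character vector of tokens, in reading order.
#' @export
tokenize_chars <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(text, "", fixed = TRUE)[[1L]]
  toks[!grepl("^\\s$", toks)]
}

#' @rdname tokenize_chars
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Construct a token encoder
#'
#' A token encoder is the pluggable interface through which per-token
#' contextual embeddings enter the pipeline.  It wraps a function
#' `encode(text)` returning `list(tokens = <character>, M = <n x d matrix>)`
#' with one row per token in reading order.  Sequence start/end marker
#' tokens must not appear in the output: the embedding matrix of a 7-token
#' unit has exactly 7 rows.  Real pretrained encoders can be plugged in by
#' users; the package ships deterministic mock encoders so everything runs
#' offline.
#'
#' @param encode Function `text -> list(tokens, M)`.
#' @param d Embedding dimensionality the encoder promises (default 768).
#' @param name Human-readable tag.
#' @return An object of class `token_encoder`.
#' @export
token_encoder <- function(encode, d = 768L, name = "custom") {
  stopifnot(is.function(encode), is.numeric(d), d >= 2)
  structure(list(encode = encode, d = as.integer(d), name = name),
            class = "token_encoder")
}

#' Construct a unit encoder
#'
#' A unit encoder maps a whole text unit directly to a single d-vector
#' (the sentence-embedding route, as opposed to averaging token vectors).
#'
#' @param encode Function `text -> numeric(d)`.
#' @inheritParams token_encoder
#' @return An object of class `unit_encoder`.
#' @export
unit_encoder <- function(encode, d = 768L, name = "custom") {
  stopifnot(is.function(encode), is.numeric(d), d >= 2)
  structure(list(encode = encode, d = as.integer(d), name = name),
            class = "unit_encoder")
}

# Deterministic 32-bit integer hash of a string (FNV-1a), kept < 2^31 so it
# can seed R's RNG.
.hash32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

#' Deterministic mock encoders
#'
#' `hash_token_encoder()` maps every token to a fixed pseudo-random
#' d-vector derived from a hash of the token string and `seed`;
#' `hash_unit_encoder()` does the same for whole units.  Both are pure
#' functions of their inputs, so repeated encodings are identical — they
#' emulate the *shape* of contextual-embedding pipelines (not their
#' semantics) and let every test run without pretrained weights.
#'
#' @param d Embedding dimensionality (default 768).
#' @param seed Integer mixed into the hash.
#' @param tokenizer Tokenization function, see [tokenize_chars()].
#' @return A [token_encoder()] / [unit_encoder()].
#' @export
hash_token_encoder <- function(d = 768L, seed = 1L, tokenizer = tokenize_chars) {
  d <- as.integer(d)
  enc <- function(text) {
    toks <- tokenizer(text)
    M <- t(vapply(toks, function(tk) {
      withr::with_seed((.hash32(tk) + seed) %% .Machine$integer.max,
                       stats::rnorm(d))
    }, numeric(d)))
    dimnames(M) <- NULL
    if (length(toks) == 1L) M <- matrix(M, nrow = 1L)
    list(tokens = toks, M = M)
  }
  token_encoder(enc, d = d, name = sprintf("hash_token(d=%d,seed=%d)", d, seed))
}

#' @rdname hash_token_encoder
#' @export
hash_unit_encoder <- function(d = 768L, seed = 2L) {
  d <- as.integer(d)
  enc <- function(text) {
    withr::with_seed((.hash32(paste0("unit:", text)) + seed) %%
                       .Machine$integer.max,
                     stats::rnorm(d))
  }
  unit_encoder(enc, d = d, name = sprintf("hash_unit(d=%d,seed=%d)", d, seed))
}

#' Encode one text unit into an embedding matrix
#'
#' Runs the encoder and validates its contract: at least one token, one
#' finite d-vector per token, rows in reading order.
#'
#' @param text Unit text; must be non-empty after whitespace stripping.
#' @param encoder A [token_encoder()].
#' @param unit_id Optional identifier attached to the result.
#' @return A list of class `embedding_matrix` with fields `unit_id`,
#'   `tokens`, `M` (n_tokens x d) and `source`.
#' @export
encode_unit <- function(text, encoder, unit_id = NA_character_) {
  stopifnot(inherits(encoder, "token_encoder"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("encode_unit: text is empty after whitespace stripping (unit_id=",
         unit_id, ")", call. = FALSE)
  out <- encoder$encode(text)
  if (!is.list(out) || is.null(out$tokens) || is.null(out$M))
    stop("encoder contract violated: encode() must return list(tokens, M)",
         call. = FALSE)
  M <- as.matrix(out$M)
  if (length(out$tokens) == 0L || nrow(M) == 0L)
    stop("encode_unit: encoder returned zero tokens for unit_id=", unit_id,
         call. = FALSE)
  if (nrow(M) != length(out$tokens))
    stop("encoder contract violated: one matrix row per token required",
         call. = FALSE)
  if (!all(is.finite(M)))
    stop("encoder contract violated: non-finite embedding entries", call. = FALSE)
  structure(list(unit_id = unit_id, tokens = out$tokens, M = M,
                 source = "token_encoder"),
            class = "embedding_matrix")
}
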