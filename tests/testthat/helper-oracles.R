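# Independently coded brute-force oracles. These deliberately use naive
# loops and textbook formulas, not the package's vectorized paths.

oracle_cumdist <- function(M, metric) {
  n <- nrow(M)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    u <- M[i, ]; v <- M[i + 1, ]
    total <- total + switch(metric,
      euclidean = sqrt(sum((u - v)^2)),
      manhattan = sum(abs(u - v)),
      chebyshev = max(abs(u - v)),
      cosine = 1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))
  }
  total
}

oracle_colmean <- function(M) {
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) out[j] <- sum(M[, j]) / nrow(M)
  out
}

oracle_norms <- function(v) {
  e <- 0; m <- 0; ch <- 0
  for (x in v) {
    e <- e + x^2; m <- m + abs(x); ch <- max(ch, abs(x))
  }
  c(sqrt(e), m, ch)
}

# O(n^3) gift-wrapping convex hull on distinct 2-D points; returns vertex
# indices in traversal order (possibly length 1 or 2 for degenerate sets).
oracle_hull_vertices <- function(P) {
  P <- unique(P)
  n <- nrow(P)
  if (n <= 2) return(P)
  start <- order(P[, 2], P[, 1])[1]
  hull <- start
  cur <- start
  repeat {
    cand <- NA
    for (j in seq_len(n)) {
      if (j == cur) next
      if (is.na(cand)) { cand <- j; next }
      cross <- (P[cand, 1] - P[cur, 1]) * (P[j, 2] - P[cur, 2]) -
               (P[cand, 2] - P[cur, 2]) * (P[j, 1] - P[cur, 1])
      dc <- sum((P[cand, ] - P[cur, ])^2)
      dj <- sum((P[j, ] - P[cur, ])^2)
      if (cross < -1e-12 || (abs(cross) <= 1e-12 && dj > dc)) cand <- j
    }
    if (cand == start) break
    hull <- c(hull, cand)
    cur <- cand
    if (length(hull) > n) stop("gift wrapping failed")
  }
  P[hull, , drop = FALSE]
}

oracle_hull_perimeter_area <- function(P) {
  H <- oracle_hull_vertices(P)
  m <- nrow(H)
  if (m == 1) return(c(perimeter = 0, area = 0))
  if (m == 2) {
    return(c(perimeter = 2 * sqrt(sum((H[1, ] - H[2, ])^2)), area = 0))
  }
  per <- 0; sh <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    per <- per + sqrt(sum((H[i, ] - H[j, ])^2))
    sh <- sh + H[i, 1] * H[j, 2] - H[j, 1] * H[i, 2]
  }
  c(perimeter = per, area = abs(sh) / 2)
}

# one-hot mock encoder over a fixed alphabet, for exactly checkable rows
onehot_encoder <- function(alphabet = letters, tokenizer = tokenize_chars) {
  V <- length(alphabet)
  token_encoder(function(text) {
    toks <- tokenizer(text)
    M <- matrix(0, length(toks), V)
    for (i in seq_along(toks)) M[i, match(toks[i], alphabet)] <- 1
    list(tokens = toks, M = M)
  }, d = V, name = "onehot")
}
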