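test_that("cumulative distances match hand values on simple geometry", {
  M <- rbind(c(0, 0), c(3, 4))
  expect_equal(cumulative_distance(M, "euclidean"), 5)
  expect_equal(cumulative_distance(M, "manhattan"), 7)
  expect_equal(cumulative_distance(M, "chebyshev"), 4)
  expect_equal(cumulative_distance(rbind(c(1, 0), c(0, 1)), "cosine"), 1)
  expect_equal(cumulative_distance(rbind(c(1, 0), c(-1, 0)), "cosine"), 2)
  # single token: every cumulative distance is 0
  for (m in c("euclidean", "cosine", "manhattan", "chebyshev"))
    expect_equal(cumulative_distance(matrix(rnorm(5), 1), m), 0)
})

test_that("cumulative distances agree with the pairwise-loop oracle", {
  set.seed(11)
  M <- matrix(rnorm(5 * 768), 5, 768)
  for (m in c("euclidean", "cosine", "manhattan", "chebyshev"))
    expect_equal(cumulative_distance(M, m), oracle_cumdist(M, m),
                 tolerance = 1e-10)
})

test_that("zero-norm rows give an explicit cosine error, not NaN", {
  M <- rbind(c(0, 0), c(1, 1))
  expect_error(cumulative_distance(M, "cosine"), "zero-norm")
})

test_that("unit vector and norms match loop oracles", {
  expect_equal(unname(unit_vector_from_tokens(rbind(c(0, 2), c(2, 0)))[1:2]),
               c(1, 1))
  one <- matrix(rnorm(10), 1)
  expect_equal(as.numeric(unit_vector_from_tokens(one)), as.numeric(one))
  set.seed(12)
  M <- matrix(rnorm(7 * 768), 7, 768)
  expect_equal(as.numeric(unit_vector_from_tokens(M)), oracle_colmean(M),
               tolerance = 1e-12)
  expect_equal(unname(vector_norms(c(3, 4))), c(5, 7, 4))
  expect_equal(unname(vector_norms(rep(0, 5))), c(0, 0, 0))
  v <- rnorm(768)
  expect_equal(unname(vector_norms(v)), oracle_norms(v), tolerance = 1e-12)
})

test_that("2-D projection preserves geometry that is already planar", {
  set.seed(13)
  A <- matrix(rnorm(9 * 2), 9, 2)
  R <- qr.Q(qr(matrix(rnorm(768 * 2), 768, 2)))  # 768x2 orthonormal
  M <- A %*% t(R)
  P <- project_2d(M)$P
  dist_orig <- as.matrix(dist(A))
  dist_proj <- as.matrix(dist(P))
  expect_equal(dist_proj, dist_orig, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("projection handles degenerate inputs", {
  M <- matrix(1, 4, 10)  # identical rows
  pr <- project_2d(M)
  expect_true(all(pr$P == 0))
  expect_true(pr$degenerate)
  expect_true(project_2d(matrix(rnorm(10), 1))$degenerate)
  # rank-1 input: second component zero-filled
  r1 <- outer(1:5, rnorm(10))
  expect_equal(project_2d(r1)$P[, 2], rep(0, 5))
})

test_that("hull features on squares, lines and sign flips", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(hull_features(sq),
               c(neighbor_sum = 3, perimeter = 4, area = 1))
  line <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(hull_features(line),
               c(neighbor_sum = 2, perimeter = 4, area = 0))
  expect_equal(hull_features(matrix(rnorm(2), 1)),
               c(neighbor_sum = 0, perimeter = 0, area = 0))
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(hull_features(two),
               c(neighbor_sum = 5, perimeter = 10, area = 0))
  set.seed(14)
  P <- matrix(rnorm(20), 10, 2)
  for (flip in list(c(-1, 1), c(1, -1), c(-1, -1)))
    expect_equal(hull_features(sweep(P, 2, flip, `*`)), hull_features(P))
})

test_that("hull perimeter/area match the gift-wrapping + shoelace oracle", {
  set.seed(15)
  P <- matrix(rnorm(20), 10, 2)
  hf <- hull_features(P)
  or <- oracle_hull_perimeter_area(P)
  expect_equal(hf[["perimeter"]], or[["perimeter"]], tolerance = 1e-10)
  expect_equal(hf[["area"]], or[["area"]], tolerance = 1e-10)
})

test_that("metric chain and scaling laws hold across random units", {
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(2:12, 1); d <- sample(2:32, 1)
    M <- matrix(rnorm(n * d), n, d)
    e <- cumulative_distance(M, "euclidean")
    mn <- cumulative_distance(M, "manhattan")
    ch <- cumulative_distance(M, "chebyshev")
    co <- cumulative_distance(M, "cosine")
    expect_true(ch <= e + 1e-12 && e <= mn + 1e-12 && mn <= d * ch + 1e-9)
    expect_true(co >= 0 && co <= 2 * (n - 1) + 1e-12)
    c_ <- runif(1, 0.1, 5)
    expect_equal(cumulative_distance(c_ * M, "euclidean"), c_ * e)
    expect_equal(cumulative_distance(c_ * M, "cosine"), co,
                 tolerance = 1e-9)
    hf <- hull_features(project_2d(M))
    hf_c <- hull_features(project_2d(c_ * M))
    expect_equal(hf_c[["perimeter"]], c_ * hf[["perimeter"]],
                 tolerance = 1e-8)
    expect_equal(hf_c[["area"]], c_^2 * hf[["area"]], tolerance = 1e-8)
    # identical-direction vectors have zero cumulative cosine distance
    v <- rnorm(d)
    expect_equal(cumulative_distance(outer(1:4, v), "cosine"), 0,
                 tolerance = 1e-12)
  }
})

test_that("encode_unit enforces the encoder contract", {
  enc <- onehot_encoder()
  e <- encode_unit("abc", enc, unit_id = "u1")
  expect_equal(e$tokens, c("a", "b", "c"))
  expect_equal(e$M, rbind(diag(26)[1, ], diag(26)[2, ], diag(26)[3, ]))
  expect_error(encode_unit("   ", enc), "empty")
  bad <- token_encoder(function(text) list(tokens = character(0),
                                           M = matrix(0, 0, 2)), d = 2)
  expect_error(encode_unit("abc", bad), "zero tokens")
})

test_that("hash encoder yields the documented shape and is deterministic", {
  enc <- hash_token_encoder(d = 768, seed = 3)
  e1 <- encode_unit("seven ch", enc)   # 7 non-space characters
  expect_equal(dim(e1$M), c(7, 768))
  e2 <- encode_unit("seven ch", enc)
  expect_identical(e1$M, e2$M)
  u <- hash_unit_encoder(d = 64, seed = 4)
  expect_identical(u$encode("text one"), u$encode("text one"))
  expect_false(isTRUE(all.equal(u$encode("text one"), u$encode("text two"))))
})

test_that("compute_unit_features composes its sub-operations", {
  tok <- hash_token_encoder(d = 64, seed = 5)
  uenc <- hash_unit_encoder(d = 64, seed = 6)
  text <- "abcdefg"
  row <- compute_unit_features(text, tok, uenc, unit_id = "u7")
  emb <- encode_unit(text, tok)
  expect_equal(row$n_tokens, 7)
  expect_equal(row$total_euclidean, cumulative_distance(emb$M, "euclidean"))
  expect_equal(row$total_cosine, cumulative_distance(emb$M, "cosine"))
  expect_equal(row$norm_euclid_tok,
               vector_norms(unit_vector_from_tokens(emb$M))[["euclid"]])
  expect_equal(row$norm_manhattan_unit,
               vector_norms(uenc$encode(text))[["manhattan"]])
  hf <- hull_features(project_2d(emb$M))
  expect_equal(row$hull_area, hf[["area"]])
  expect_equal(row$hull_neighbor_sum, hf[["neighbor_sum"]])
  expect_true(is.na(row$cumulative_surprisal))
})

test_that("one-token units give zero distances and zero hull", {
  tok <- hash_token_encoder(d = 32, seed = 7)
  uenc <- hash_unit_encoder(d = 32, seed = 8)
  row <- compute_unit_features("x", tok, uenc, unit_id = "u1")
  expect_equal(row$total_euclidean, 0)
  expect_equal(row$total_cosine, 0)
  expect_equal(c(row$hull_neighbor_sum, row$hull_perimeter, row$hull_area),
               c(0, 0, 0))
  v <- encode_unit("x", tok)$M[1, ]
  expect_equal(row$norm_euclid_tok, vector_norms(v)[["euclid"]])
})

test_that("batch feature computation is complete and carries ids", {
  units <- tibble::tibble(unit_id = paste0("u", 1:8),
                          text = c("ab", "cde", "fg hi", "jklmn", "op",
                                   "qrs", "tuv wx", "yz"),
                          material = "m1")
  out <- compute_features(units, hash_token_encoder(d = 16, seed = 9),
                          hash_unit_encoder(d = 16, seed = 10),
                          masked_lm = mock_lm_uniform(50))
  expect_equal(nrow(out), 8)
  expect_equal(out$unit_id, units$unit_id)
  expect_false(anyNA(out[, embedding_feature_names()]))
  expect_true("material" %in% names(out))
  # error carries the offending unit id
  units$text[3] <- "  "
  expect_error(compute_features(units, hash_token_encoder(d = 16, seed = 9),
                                hash_unit_encoder(d = 16, seed = 10)),
               "unit_id=u3")
})
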