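test_that("scaled dot-product attention matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    m <- sample(2:8, 1)
    dk <- sample(1:5, 1)
    dv <- sample(1:5, 1)
    Q <- matrix(rnorm(n * dk), n)
    K <- matrix(rnorm(m * dk), m)
    V <- matrix(rnorm(m * dv), m)
    expect_lt(max(abs(scaled_dot_product_attention(Q, K, V) -
                        oracle_attention(Q, K, V))), 1e-6)
  }
  # single key: output equals the value row regardless of Q, K
  v <- matrix(c(3, -1), 1)
  expect_equal(scaled_dot_product_attention(matrix(5, 1, 2),
                                            matrix(-2, 1, 2), v), v)
  # identical keys share the weight equally
  K2 <- matrix(1, 2, 3)
  V2 <- rbind(c(0, 0), c(2, 4))
  r <- scaled_dot_product_attention(matrix(rnorm(3), 1), K2, V2,
                                    return_weights = TRUE)
  expect_equal(as.vector(r$weights), c(0.5, 0.5))
  expect_equal(as.vector(r$output), c(1, 2))
})

test_that("attention weights are a masked probability distribution", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    Q <- matrix(rnorm(n * 4), n)
    K <- matrix(rnorm(n * 4), n)
    V <- matrix(rnorm(n * 3), n)
    mask <- local_attention_mask(n, 3L)
    r <- scaled_dot_product_attention(Q, K, V, mask, return_weights = TRUE)
    expect_true(all(r$weights >= 0 & r$weights <= 1))
    expect_lt(max(abs(rowSums(r$weights) - 1)), 1e-6)
    expect_true(all(r$weights[!mask] == 0))      # exactly zero
    expect_lt(max(abs(r$output - oracle_attention(Q, K, V, mask))), 1e-6)
  }
  full_mask <- matrix(FALSE, 2, 2)
  expect_error(scaled_dot_product_attention(matrix(0, 2, 1), matrix(0, 2, 1),
                                            matrix(0, 2, 1), full_mask),
               "fully masked")
})

test_that("local attention mask is the banded window pattern", {
  m <- local_attention_mask(5L, 3L)
  expect_equal(sum(m), 13L)
  expect_equal(rowSums(m), c(2, 3, 3, 3, 2), ignore_attr = TRUE)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m)))
  # window covering the whole sequence = global
  expect_true(all(local_attention_mask(4L, 7L)))
  # window 1 = identity; attention returns V
  id <- local_attention_mask(3L, 1L)
  expect_equal(id, diag(3) == 1, ignore_attr = TRUE)
  V <- matrix(rnorm(6), 3)
  expect_equal(scaled_dot_product_attention(matrix(rnorm(6), 3),
                                            matrix(rnorm(6), 3), V, id), V)
  expect_error(local_attention_mask(5L, 4L), "odd")
})

test_that("multi-head attention equals the per-head loop and reduces at h=1", {
  cfg1 <- attention_config(n_heads = 1L, d_model = 3L, d_k = 3L, d_v = 3L,
                           mode = "global")
  X <- matrix(rnorm(12), 4)
  id3 <- diag(3)
  params <- list(Wq = list(id3), Wk = list(id3), Wv = list(id3), Wo = id3)
  expect_equal(multi_head_attention(X, cfg1, params),
               scaled_dot_product_attention(X, X, X))

  set.seed(3)
  cfg2 <- attention_config(n_heads = 2L, d_model = 8L, d_k = 3L, d_v = 2L,
                           mode = "global")
  params2 <- list(Wq = replicate(2, matrix(rnorm(24), 8), simplify = FALSE),
                  Wk = replicate(2, matrix(rnorm(24), 8), simplify = FALSE),
                  Wv = replicate(2, matrix(rnorm(16), 8), simplify = FALSE),
                  Wo = matrix(rnorm(32), 4))
  for (n in c(1, 5, 9)) {
    X <- matrix(rnorm(n * 8), n)
    got <- multi_head_attention(X, cfg2, params2)
    expect_equal(dim(got), c(n, 8L))
    heads <- lapply(1:2, function(i)
      oracle_attention(X %*% params2$Wq[[i]], X %*% params2$Wk[[i]],
                       X %*% params2$Wv[[i]]))
    expect_lt(max(abs(got - do.call(cbind, heads) %*% params2$Wo)), 1e-6)
  }
  bad <- params2
  bad$Wo <- matrix(0, 5, 8)
  expect_error(multi_head_attention(X, cfg2, bad), "Wo")
})

test_that("positional encoding satisfies its closed forms", {
  pe <- positional_encoding(10L, 6L)
  expect_equal(pe[1, ], rep(c(0, 1), 3))            # pos 0: sin 0, cos 0
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12) # PE(1, 0) = sin(1)
  # same first column for any d
  expect_equal(positional_encoding(3L, 12L)[2, 1], sin(1))
  # Pythagorean identity over every (pos, i) pair
  odd <- pe[, seq(1, 5, by = 2)]^2 + pe[, seq(2, 6, by = 2)]^2
  expect_lt(max(abs(odd - 1)), 1e-12)
  expect_error(positional_encoding(4L, 5L), "even")
})

test_that("encoder layer is shape-preserving and local matches global at full window", {
  set.seed(11)
  d <- 6L
  make_params <- function() {
    c(list(Wq = replicate(2, matrix(rnorm(d * 3), d), simplify = FALSE),
           Wk = replicate(2, matrix(rnorm(d * 3), d), simplify = FALSE),
           Wv = replicate(2, matrix(rnorm(d * 3), d), simplify = FALSE),
           Wo = matrix(rnorm(6 * d), 6)),
      list(ln1_g = rep(1, d), ln1_b = rep(0, d),
           W1 = matrix(rnorm(d * 2 * d), d), b1 = rep(0, 2 * d),
           W2 = matrix(rnorm(2 * d * d), 2 * d), b2 = rep(0, d),
           ln2_g = rep(1, d), ln2_b = rep(0, d)))
  }
  params <- make_params()
  for (n in c(2L, 7L, 12L)) {
    X <- matrix(rnorm(n * d), n)
    cfg_l <- attention_config(2L, d, 3L, 3L, mode = "local",
                              window = 2L * n - 1L)
    cfg_g <- attention_config(2L, d, 3L, 3L, mode = "global")
    out_l <- transformer_encoder_layer(X, cfg_l, params)
    out_g <- transformer_encoder_layer(X, cfg_g, params)
    expect_equal(dim(out_l), dim(X))
    expect_lt(max(abs(out_l - out_g)), 1e-6)
  }
  # zeroed attention output projection leaves the feed-forward-only transform
  pz <- params
  pz$Wo <- matrix(0, 6, d)
  X <- matrix(rnorm(5 * d), 5)
  out <- transformer_encoder_layer(X, attention_config(2L, d, 3L, 3L,
                                                       mode = "global"), pz)
  z1 <- lgct:::layer_norm_ref(X, pz$ln1_g, pz$ln1_b)
  ff <- lgct:::elu_ref(sweep(z1 %*% pz$W1, 2, pz$b1, `+`)) %*% pz$W2
  ref <- lgct:::layer_norm_ref(z1 + sweep(ff, 2, pz$b2, `+`),
                               pz$ln2_g, pz$ln2_b)
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("engine banded attention agrees with the masked reference implementation", {
  set.seed(5)
  for (rep in 1:10) {
    Tt <- sample(4:16, 1)
    S <- sample(1:3, 1)
    dk <- sample(2:4, 1)
    window <- sample(c(1L, 3L, 5L), 1)
    Q <- matrix(rnorm(Tt * S * dk), Tt * S)
    K <- matrix(rnorm(Tt * S * dk), Tt * S)
    V <- matrix(rnorm(Tt * S * dk), Tt * S)
    half <- (window - 1L) / 2L
    eng <- lgct:::band_attn_fwd(Q, K, V, Tt, half)$out
    mask <- local_attention_mask(Tt, window)
    for (s in seq_len(S)) {
      rows <- (s - 1L) * Tt + seq_len(Tt)
      ref <- scaled_dot_product_attention(Q[rows, , drop = FALSE],
                                          K[rows, , drop = FALSE],
                                          V[rows, , drop = FALSE], mask)
      expect_lt(max(abs(eng[rows, ] - ref)), 1e-6)
    }
  }
})
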