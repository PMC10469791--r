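test_that("forward pass produces softmax rows and is deterministic per seed", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  bands <- tiny_bands(N = 4L)
  out <- lgct:::model_forward_core(m, bands)
  expect_equal(dim(out$probs), c(4L, 2L))
  expect_lt(max(abs(rowSums(out$probs) - 1)), 1e-6)
  expect_true(all(out$probs >= 0 & out$probs <= 1))

  m2 <- build_model(cfg, tiny_montage())
  expect_identical(m$params, m2$params)
  out2 <- lgct:::model_forward_core(m2, bands)
  expect_identical(out$probs, out2$probs)
  # evaluation mode bit-identical across repeated calls
  expect_identical(lgct:::model_forward_core(m, bands)$probs, out$probs)

  # both class counts build and run
  cfg4 <- tiny_model_config()
  cfg4$n_classes <- 4L
  m4 <- build_model(cfg4, tiny_montage())
  expect_equal(dim(lgct:::model_forward_core(m4, tiny_bands(N = 2L))$probs),
               c(2L, 4L))
})

test_that("temporal block: pooling arithmetic, additive fusion, locality", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  ep <- tiny_epochs(n_trials = 3L, n_samples = 40L)
  f <- temporal_block(ep$data, m)
  T1 <- (40L - 10L) %/% 5L + 1L
  expect_equal(dim(f), c(3L, 4L, 2L, T1))

  # zeroing the transformer path's output projection leaves the pure CNN path
  mz <- m
  mz$params[["b1.tproj.W"]][] <- 0
  mz$params[["b1.tproj.b"]][] <- 0
  f_cnn <- temporal_block(ep$data, mz)
  m_wo <- make_ablation_variant(cfg, "w/o_trans", tiny_montage())
  # align the conv weights and batch-norm parameters, then outputs must agree
  for (nm in c("b1.tconv.W", "b1.tconv.b", "b1.tbn.g", "b1.tbn.b"))
    m_wo$params[[nm]] <- mz$params[[nm]]
  expect_equal(temporal_block(ep$data, m_wo), f_cnn, tolerance = 1e-10)

  # locality: both paths share the receptive field, so perturbing a sample
  # far outside position t's kernel window leaves the pre-pooling feature at
  # t unchanged. Probe via a no-pooling configuration.
  cfg_np <- tiny_model_config()
  cfg_np$temporal$pool_len <- 1L
  cfg_np$temporal$pool_stride <- 1L
  mnp <- build_model(cfg_np, tiny_montage())
  x1 <- ep$data
  x2 <- x1
  x2[1, 1, 40] <- x2[1, 1, 40] + 100      # far from t = 5 (kernel/window 5)
  f1 <- temporal_block(x1, mnp)
  f2 <- temporal_block(x2, mnp)
  # batch-norm statistics are global; compare normalized inputs instead by
  # using eval mode with frozen buffers (already eval) -> BN uses running
  # stats, so the probe is exact
  expect_equal(f1[1, 1, , 5], f2[1, 1, , 5], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f1[1, 1, , 38], f2[1, 1, , 38])))
})

test_that("spatial block: antisymmetry, channel bookkeeping, ablation contract", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  # tie left/right path weights; mirrored input must zero the difference path
  m$params[["b1.sp_r.W"]] <- m$params[["b1.sp_l.W"]]
  m$params[["b1.sp_r.b"]] <- m$params[["b1.sp_l.b"]]
  mont <- tiny_montage()             # C1 C2 C3 C4: left (1,3), right (2,4)
  T1 <- 7L
  f <- array(rnorm(2 * 4 * 2 * T1), dim = c(2, 4, 2, T1))
  f[, mont$right_idx, , ] <- f[, mont$left_idx, , ]
  out <- spatial_block(f, m)
  S <- cfg$spatial$n_filters_per_path
  # second half of the feature channels is the (normalized, activated) diff;
  # with zero pre-BN diff it equals act(bn(0)), identical across inputs:
  diff_feats <- out[, S + seq_len(S), ]
  expect_equal(diff_feats[1, , ], diff_feats[2, , ], tolerance = 1e-10)

  # ablation: w/o_diff-hemi output equals the all-channel path alone
  m_wo <- make_ablation_variant(cfg, "w/o_diff-hemi", tiny_montage())
  for (nm in c("b1.sp_all.W", "b1.sp_all.b"))
    m_wo$params[[nm]] <- m$params[[nm]]
  m_wo$params[["b1.sbn.g"]] <- m$params[["b1.sbn.g"]][seq_len(S)]
  m_wo$params[["b1.sbn.b"]] <- m$params[["b1.sbn.b"]][seq_len(S)]
  out_wo <- spatial_block(f, m_wo)
  expect_equal(out_wo, out[, seq_len(S), , drop = FALSE], tolerance = 1e-10)
})

test_that("KU 20-channel montage hemisphere paths use 9 channels each", {
  mont <- ku_motor_montage()
  cfg <- model_config(n_channels = 20L, n_samples = 40L, n_classes = 2L,
                      temporal = list(n_filters = 2L, kernel_len = 5L,
                                      pool_len = 10L, pool_stride = 5L),
                      n_heads = 2L, token_embed_dim = 4L,
                      spatial = list(n_filters_per_path = 2L),
                      tdense = list(n_layers_per_branch = 3L, growth = 4L,
                                    reduce_filters = 4L, kernel_len = 3L),
                      seed = 1L)
  m <- build_model(cfg, mont)
  # hemisphere path weight rows = 9 channels x temporal filters
  expect_equal(nrow(m$params[["b1.sp_l.W"]]), 9L * 2L)
  expect_equal(nrow(m$params[["b1.sp_r.W"]]), 9L * 2L)
  expect_equal(nrow(m$params[["b1.sp_all.W"]]), 20L * 2L)
})

test_that("T-Dense unit implements dense connectivity and widths", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  g <- cfg$tdense$growth
  K0 <- 2L * cfg$spatial$n_filters_per_path
  # layer k of the CNN branch consumes input_width + (k-1) * growth channels
  for (l in 1:3) {
    W <- m$params[[sprintf("b1.td_cnn%d.W", l)]]
    expect_equal(dim(W)[2], K0 + (l - 1L) * g)
  }
  # structural dense connectivity: layer 3 sees input + layer1 + layer2
  expect_equal(dim(m$params[["b1.td_cnn3.W"]])[2], K0 + 2L * g)

  # unit output width = 2 branches x L x growth; block reduces to
  # reduce_filters regardless of growth
  T1 <- 7L
  f <- array(rnorm(2 * K0 * T1), dim = c(2, K0, T1))
  u <- tdense_unit(f, m)
  expect_equal(dim(u)[2], 2L * 3L * g)
  blk <- tdense_block(f, m)
  expect_equal(dim(blk)[2], cfg$tdense$reduce_filters)

  # w/o_T-dense differs from the dense unit on random input (same seed)
  m_wo <- make_ablation_variant(cfg, "w/o_T-dense", tiny_montage())
  blk_wo <- tdense_block(f, m_wo)
  expect_equal(dim(blk_wo)[2], cfg$tdense$reduce_filters)
  expect_false(isTRUE(all.equal(blk, blk_wo)))
})

test_that("every trainable parameter receives a nonzero gradient", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  bands <- tiny_bands(N = 4L)
  y <- c(0L, 1L, 0L, 1L)
  Y <- matrix(0, 4, 2)
  Y[cbind(1:4, y + 1L)] <- 1
  fwd <- lgct:::model_forward_core(m, bands, training = TRUE,
                                   keep_cache = TRUE)
  genv <- new.env(parent = emptyenv())
  lgct:::model_backward_core(m, (fwd$probs - Y) / 4, fwd$cache, genv)
  grads <- as.list(genv)
  expect_setequal(names(grads), names(m$params))
  dead <- names(m$params)[!vapply(names(m$params),
                                  function(nm) any(grads[[nm]] != 0),
                                  logical(1))]
  expect_identical(dead, character(0))
})

test_that("analytic gradients match finite differences across layer types", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  bands <- tiny_bands(N = 3L)
  Y <- matrix(0, 3, 2)
  Y[cbind(1:3, c(1, 2, 1))] <- 1
  lossfn <- function(model)
    cross_entropy(lgct:::model_forward_core(model, bands,
                                            training = TRUE)$probs, Y)
  fwd <- lgct:::model_forward_core(m, bands, training = TRUE,
                                   keep_cache = TRUE)
  genv <- new.env(parent = emptyenv())
  lgct:::model_backward_core(m, (fwd$probs - Y) / 3, fwd$cache, genv)
  grads <- as.list(genv)
  # probe one element of one representative parameter per layer family
  probe <- c("b1.tconv.W", "b1.lift.W", "b1.enc.Wq", "b1.enc.W1",
             "b1.enc.ln1_g", "b1.tproj.W", "b1.tbn.g", "b2.sp_l.W",
             "b2.td_cnn2.W", "b3.td_tr1.Wv", "b3.td_tr3_proj.W",
             "b1.td_red.W", "head.W")
  set.seed(123)
  for (nm in probe) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
    gnum <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
    gan <- grads[[nm]][i]
    expect_lt(abs(gnum - gan) / max(1e-4, abs(gnum) + abs(gan)), 1e-4)
  }
})

test_that("band branches are independent before fusion", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  bands <- tiny_bands(N = 2L)
  base <- lgct:::model_forward_core(m, bands, keep_cache = TRUE)
  m2 <- m
  m2$params[["b1.tconv.W"]][] <- rnorm(length(m2$params[["b1.tconv.W"]]))
  pert <- lgct:::model_forward_core(m2, bands, keep_cache = TRUE)
  # band 2's T-Dense output unchanged by a band-1 weight perturbation
  expect_identical(pert$cache$bands[[2]]$tdense$unit_out,
                   base$cache$bands[[2]]$tdense$unit_out)
  expect_false(isTRUE(all.equal(pert$cache$bands[[1]]$tdense$unit_out,
                                base$cache$bands[[1]]$tdense$unit_out)))
})

test_that("count_parameters: closed forms, ablation orderings, attention counter", {
  # lone fully connected layer 10 -> 2 with bias
  expect_equal(count_parameters(list(W = matrix(0, 10, 2), b = numeric(2))),
               22L)
  # 1-D conv: 8 filters, kernel 25, 1 input channel, bias
  expect_equal(count_parameters(list(W = array(0, c(25, 1, 8)),
                                     b = numeric(8))), 208L)

  cfg <- tiny_model_config()
  full <- build_model(cfg, tiny_montage())
  # independent audit: recompute the expected total from the architecture
  enc_n <- function(d, dk) 3 * (d * dk + dk) + (dk * d + d) +
    2 * d + (d * 2 * d + 2 * d) + (2 * d * d + d) + 2 * d
  d <- cfg$token_embed_dim
  Ftemp <- cfg$temporal$n_filters
  S <- cfg$spatial$n_filters_per_path
  K0 <- 2L * S
  g <- cfg$tdense$growth
  kt <- cfg$tdense$kernel_len
  per_band <- (5 * 1 * Ftemp + Ftemp) +                      # temporal conv
    (1 * d + d) + enc_n(d, d) + (d * Ftemp + Ftemp) +        # lift+enc+proj
    2 * Ftemp +                                              # temporal BN
    (4 * Ftemp * S + S) + 2 * (2 * Ftemp * S + S) + 2 * K0 + # spatial
    sum(vapply(1:3, function(l) {
      w <- K0 + (l - 1L) * g
      (kt * w * g + g) + 2 * g +                             # cnn layer + bn
        enc_n(w, w) + (w * g + g) + 2 * g                    # tr layer
    }, 1)) +
    (1 * 6 * g * 4 + 4) + 2 * 4                              # reduce + bn
  T1 <- 7L
  expected <- 3L * per_band + (3L * 4L * T1 * 2L + 2L)       # + head
  expect_equal(count_parameters(full), expected)

  wo_t <- make_ablation_variant(cfg, "w/o_Trans", tiny_montage())
  wo_h <- make_ablation_variant(cfg, "w/o_Diff-hemi", tiny_montage())
  wo_d <- make_ablation_variant(cfg, "w/o_T-dense", tiny_montage())
  expect_lt(count_parameters(wo_t), count_parameters(full))
  expect_lt(count_parameters(wo_h), count_parameters(full))
  expect_error(make_ablation_variant(cfg, "w/o_everything"), "unknown")

  # the ablated model performs no attention computation
  reset_attention_call_count()
  invisible(lgct:::model_forward_core(wo_t, tiny_bands(N = 2L)))
  expect_equal(attention_call_count(), 0L)
  invisible(lgct:::model_forward_core(full, tiny_bands(N = 2L)))
  expect_gt(attention_call_count(), 0L)
  reset_attention_call_count()
})

test_that("full model with zeroed transformer projections mirrors w/o_trans", {
  cfg <- tiny_model_config()
  full <- build_model(cfg, tiny_montage())
  for (b in 1:3) {
    full$params[[sprintf("b%d.tproj.W", b)]][] <- 0
    full$params[[sprintf("b%d.tproj.b", b)]][] <- 0
    for (l in 1:3) {
      full$params[[sprintf("b%d.td_tr%d_proj.W", b, l)]][] <- 0
      full$params[[sprintf("b%d.td_tr%d_proj.b", b, l)]][] <- 0
    }
  }
  wo <- make_ablation_variant(cfg, "w/o_trans", tiny_montage())
  # match the remaining weights; the transformer-branch slots of the full
  # model's reduce/head layers must also be matched where they act on the
  # (now constant) transformer features, so compare only the CNN-fed
  # channels: instead verify the temporal stage only.
  for (nm in c("b1.tconv.W", "b1.tconv.b", "b1.tbn.g", "b1.tbn.b"))
    wo$params[[nm]] <- full$params[[nm]]
  ep <- tiny_epochs(n_trials = 2L, n_samples = 40L)
  expect_equal(temporal_block(ep$data, wo), temporal_block(ep$data, full),
               tolerance = 1e-10)
})

test_that("checkpoint save/load reproduces outputs bit-for-bit", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, tiny_montage())
  bands <- tiny_bands(N = 2L)
  # populate batch-norm running statistics
  invisible(lgct:::model_forward_core(m, bands, training = TRUE))
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(m2$params, m$params)
  expect_identical(lgct:::model_forward_core(m2, bands)$probs,
                   lgct:::model_forward_core(m, bands)$probs)
  expect_error(build_model(model_config(1L, 40L, 2L), tiny_montage()),
               "n_channels")
})
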