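#' Model configuration
#'
#' All architecture hyperparameters of the three-branch network in one place.
#' Each frequency band feeds an identical-structure branch: a temporal block
#' (1-D CNN fused with a windowed local-attention encoder sharing the CNN's
#' receptive field), a spatial block (all-channel path plus a
#' hemisphere-difference path), and a T-Dense block (densely connected CNN and
#' global-transformer branches followed by a dimension-reducing convolution).
#' Branch outputs are concatenated into a single fully connected softmax
#' classifier.
#'
#' @param n_channels,n_samples,n_classes input geometry and number of classes.
#' @param temporal list: `n_filters`, `kernel_len` (odd, samples; also the
#'   local attention window), `pool_len`, `pool_stride`.
#' @param n_heads attention heads (`h = 2` by default).
#' @param token_embed_dim width tokens are lifted to before attention; must be
#'   even and divisible by `n_heads`.
#' @param spatial list: `n_filters_per_path`.
#' @param tdense list: `n_layers_per_branch` (>= 2), `growth` (even),
#'   `reduce_filters`, `kernel_len` (odd).
#' @param activation `"elu"` (default) or `"relu"`.
#' @param dropout_rate dropout probability used model-wide during training.
#' @param temporal_fusion `"add"` (default) or `"concat"`: how the CNN and
#'   local-transformer temporal features are combined.
#' @param variant `"full"` or an ablation: `"wo_trans"` (no attention paths),
#'   `"wo_diff_hemi"` (all-channel spatial path only), `"wo_tdense"` (plain
#'   CNN stack of equal depth instead of the dense unit).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `lgct_model_config`.
#' @export
model_config <- function(n_channels, n_samples, n_classes,
                         temporal = list(n_filters = 8L, kernel_len = 25L,
                                         pool_len = 75L, pool_stride = 15L),
                         n_heads = 2L, token_embed_dim = 16L,
                         spatial = list(n_filters_per_path = 8L),
                         tdense = list(n_layers_per_branch = 3L, growth = 8L,
                                       reduce_filters = 16L, kernel_len = 15L),
                         activation = c("elu", "relu"),
                         dropout_rate = 0.5, temporal_fusion = c("add", "concat"),
                         variant = c("full", "wo_trans", "wo_diff_hemi",
                                     "wo_tdense"),
                         seed = 1L) {
  activation <- match.arg(activation)
  temporal_fusion <- match.arg(temporal_fusion)
  variant <- match.arg(variant)
  chk <- function(cond, field, msg) if (!cond) stop("invalid config field `",
                                                    field, "`: ", msg)
  chk(n_channels >= 2L, "n_channels", "need at least one mirror pair")
  chk(n_samples >= temporal$pool_len, "n_samples", "shorter than pool_len")
  chk(n_classes >= 2L, "n_classes", "need >= 2 classes")
  chk(temporal$kernel_len %% 2L == 1L, "temporal$kernel_len",
      "must be odd (shared CNN kernel / local attention window)")
  chk(tdense$kernel_len %% 2L == 1L, "tdense$kernel_len", "must be odd")
  chk(tdense$n_layers_per_branch >= 2L, "tdense$n_layers_per_branch", ">= 2")
  chk(token_embed_dim %% 2L == 0L, "token_embed_dim",
      "must be even (positional encoding)")
  chk(token_embed_dim %% n_heads == 0L, "token_embed_dim",
      "must be divisible by n_heads")
  chk(tdense$growth %% 2L == 0L, "tdense$growth",
      "must be even (positional encoding in the transformer branch)")
  chk(spatial$n_filters_per_path %% 2L == 0L || variant == "wo_trans",
      "spatial$n_filters_per_path",
      "must be even (positional encoding in the T-Dense transformer branch)")
  cfg <- list(n_channels = as.integer(n_channels),
              n_samples = as.integer(n_samples),
              n_classes = as.integer(n_classes), n_bands = 3L,
              temporal = lapply(temporal, as.integer),
              n_heads = as.integer(n_heads),
              token_embed_dim = as.integer(token_embed_dim),
              spatial = lapply(spatial, as.integer),
              tdense = lapply(tdense, as.integer),
              activation = activation, dropout_rate = dropout_rate,
              temporal_fusion = temporal_fusion, variant = variant,
              seed = as.integer(seed))
  structure(cfg, class = "lgct_model_config")
}

#' Reference configuration (full-scale)
#'
#' The frozen reference hyperparameters for 20-channel, 4-s trials at 250 Hz:
#' temporal kernel 25 samples (0.1 s), 8 temporal filters, mean-pooling
#' 75/15, token width 16 with 2 heads, 8 spatial filters per path, T-Dense
#' 3 layers per branch with growth 8, reduction to 16 filters, ELU, dropout
#' 0.5.
#'
#' @param n_channels,n_samples,n_classes input geometry.
#' @param ... overrides passed to [model_config()].
#' @return An `lgct_model_config`.
#' @export
reference_config <- function(n_channels = 20L, n_samples = 1000L,
                             n_classes = 2L, ...) {
  model_config(n_channels, n_samples, n_classes, ...)
}

#' Reduced desk-scale configuration
#'
#' A small configuration for CPU-scale experiments (4 channels, 125 Hz, 4-s
#' trials): 4 temporal filters with kernel/window 13 (about 0.1 s at 125 Hz),
#' token width 4, 4 spatial filters per path, T-Dense growth 4 with reduction
#' to 8 filters, dropout 0.25.
#'
#' @param n_channels,n_samples,n_classes input geometry.
#' @param ... overrides passed to [model_config()].
#' @return An `lgct_model_config`.
#' @export
reduced_config <- function(n_channels = 4L, n_samples = 500L,
                           n_classes = 2L, ...) {
  model_config(n_channels, n_samples, n_classes,
               temporal = list(n_filters = 4L, kernel_len = 13L,
                               pool_len = 31L, pool_stride = 8L),
               n_heads = 2L, token_embed_dim = 4L,
               spatial = list(n_filters_per_path = 4L),
               tdense = list(n_layers_per_branch = 3L, growth = 4L,
                             reduce_filters = 8L, kernel_len = 9L),
               dropout_rate = 0.25, ...)
}

# derived dimensions shared by init / forward / backward
model_dims <- function(cfg) {
  tp <- cfg$temporal
  T1 <- (cfg$n_samples - tp$pool_len) %/% tp$pool_stride + 1L
  has_trans <- cfg$variant != "wo_trans"
  has_hemi <- cfg$variant != "wo_diff_hemi"
  Fb <- if (has_trans && cfg$temporal_fusion == "concat")
    2L * tp$n_filters else tp$n_filters
  K0 <- if (has_hemi) 2L * cfg$spatial$n_filters_per_path
        else cfg$spatial$n_filters_per_path
  L <- cfg$tdense$n_layers_per_branch
  g <- cfg$tdense$growth
  U <- if (cfg$variant == "wo_tdense") g
       else if (has_trans) 2L * L * g else L * g
  R <- cfg$tdense$reduce_filters
  list(T1 = T1, Fb = Fb, K0 = K0, L = L, g = g, U = U, R = R,
       has_trans = has_trans, has_hemi = has_hemi,
       half_local = (tp$kernel_len - 1L) %/% 2L,
       d = cfg$token_embed_dim,
       d_k = cfg$token_embed_dim %/% cfg$n_heads,
       d_v = cfg$token_embed_dim %/% cfg$n_heads,
       head_in = 3L * cfg$tdense$reduce_filters * T1)
}

# ---- parameter initialization ----------------------------------------------

init_branch_params <- function(cfg, dm) {
  tp <- cfg$temporal
  p <- list()
  p[["tconv.W"]] <- glorot(c(tp$kernel_len, 1L, tp$n_filters))
  p[["tconv.b"]] <- numeric(tp$n_filters)
  if (dm$has_trans) {
    p[["lift.W"]] <- glorot(c(1L, dm$d))
    p[["lift.b"]] <- numeric(dm$d)
    enc <- enc_params_init(dm$d, cfg$n_heads, dm$d_k, dm$d_v)
    names(enc) <- paste0("enc.", names(enc))
    p <- c(p, enc)
    p[["tproj.W"]] <- glorot(c(dm$d, tp$n_filters))
    p[["tproj.b"]] <- numeric(tp$n_filters)
  }
  p[["tbn.g"]] <- rep(1, dm$Fb)
  p[["tbn.b"]] <- numeric(dm$Fb)

  S <- cfg$spatial$n_filters_per_path
  p[["sp_all.W"]] <- glorot(c(cfg$n_channels * dm$Fb, S))
  p[["sp_all.b"]] <- numeric(S)
  if (dm$has_hemi) {
    n_hemi <- cfg$n_hemi_pairs
    p[["sp_l.W"]] <- glorot(c(n_hemi * dm$Fb, S))
    p[["sp_l.b"]] <- numeric(S)
    p[["sp_r.W"]] <- glorot(c(n_hemi * dm$Fb, S))
    p[["sp_r.b"]] <- numeric(S)
  }
  p[["sbn.g"]] <- rep(1, dm$K0)
  p[["sbn.b"]] <- numeric(dm$K0)

  g <- dm$g
  if (cfg$variant == "wo_tdense") {
    w_in <- dm$K0
    for (l in seq_len(dm$L)) {
      p[[sprintf("td_plain%d.W", l)]] <-
        glorot(c(cfg$tdense$kernel_len, w_in, g))
      p[[sprintf("td_plain%d.b", l)]] <- numeric(g)
      p[[sprintf("td_plain%d_bn.g", l)]] <- rep(1, g)
      p[[sprintf("td_plain%d_bn.b", l)]] <- numeric(g)
      w_in <- g
    }
  } else {
    for (l in seq_len(dm$L)) {
      w_l <- dm$K0 + (l - 1L) * g
      p[[sprintf("td_cnn%d.W", l)]] <- glorot(c(cfg$tdense$kernel_len, w_l, g))
      p[[sprintf("td_cnn%d.b", l)]] <- numeric(g)
      p[[sprintf("td_cnn%d_bn.g", l)]] <- rep(1, g)
      p[[sprintf("td_cnn%d_bn.b", l)]] <- numeric(g)
      if (dm$has_trans) {
        enc <- enc_params_init(w_l, cfg$n_heads, w_l %/% cfg$n_heads,
                               w_l %/% cfg$n_heads)
        names(enc) <- sprintf("td_tr%d.%s", l, names(enc))
        p <- c(p, enc)
        p[[sprintf("td_tr%d_proj.W", l)]] <- glorot(c(w_l, g))
        p[[sprintf("td_tr%d_proj.b", l)]] <- numeric(g)
        p[[sprintf("td_tr%d_bn.g", l)]] <- rep(1, g)
        p[[sprintf("td_tr%d_bn.b", l)]] <- numeric(g)
      }
    }
  }
  p[["td_red.W"]] <- glorot(c(1L, dm$U, dm$R))
  p[["td_red.b"]] <- numeric(dm$R)
  p[["td_red_bn.g"]] <- rep(1, dm$R)
  p[["td_red_bn.b"]] <- numeric(dm$R)
  p
}

#' Build the model
#'
#' Initializes all trainable parameters (Glorot-uniform weights, zero biases,
#' unit batch-norm scales) from `cfg$seed`. The three band branches have
#' independent weights; the classifier head is shared.
#'
#' @param cfg an [model_config()].
#' @param montage optional [make_montage()] matching `cfg$n_channels`; needed
#'   for the hemisphere-difference paths (defaults to a montage-free model
#'   only when the variant drops those paths).
#' @return An object of class `lgct_model` with fields `cfg`, `montage`,
#'   `params` (named list of arrays) and `buffers` (batch-norm running
#'   statistics, not trainable).
#' @export
build_model <- function(cfg, montage = NULL) {
  stopifnot(inherits(cfg, "lgct_model_config"))
  dm <- model_dims(cfg)
  if (dm$has_hemi) {
    if (is.null(montage))
      stop("montage required for the hemisphere-difference spatial paths")
    validate_montage(montage)
    if (length(montage$channel_names) != cfg$n_channels)
      stop("invalid config field `n_channels`: montage has ",
           length(montage$channel_names), " channels")
    cfg$n_hemi_pairs <- length(montage$left_idx)
  } else {
    cfg$n_hemi_pairs <- 0L
  }
  if (dm$has_trans) {
    widths <- dm$K0 + (seq_len(dm$L) - 1L) * dm$g
    if (any(widths %% 2L != 0L) || any(widths %% cfg$n_heads != 0L))
      stop("invalid config field `tdense$growth`: transformer-branch widths ",
           paste(widths, collapse = "/"),
           " must be even and divisible by n_heads")
  }
  set.seed(cfg$seed)
  params <- list()
  for (b in seq_len(cfg$n_bands)) {
    bp <- init_branch_params(cfg, dm)
    names(bp) <- sprintf("b%d.%s", b, names(bp))
    params <- c(params, bp)
  }
  params[["head.W"]] <- glorot(c(dm$head_in, cfg$n_classes))
  params[["head.b"]] <- numeric(cfg$n_classes)
  structure(list(cfg = cfg, montage = montage, params = params,
                 buffers = new.env(parent = emptyenv())),
            class = "lgct_model")
}

#' @export
print.lgct_model <- function(x, ...) {
  cat(sprintf("<lgct_model> variant=%s  %d ch x %d samples -> %d classes, %s parameters\n",
              x$cfg$variant, x$cfg$n_channels, x$cfg$n_samples,
              x$cfg$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Build an ablation variant
#'
#' @param cfg a full-model [model_config()].
#' @param which one of `"w/o_trans"` (removes local and global attention
#'   paths), `"w/o_diff-hemi"` (removes the hemisphere spatial paths),
#'   `"w/o_T-dense"` (replaces the dense unit with a plain CNN stack of equal
#'   depth). Underscored spellings are accepted.
#' @param montage montage passed to [build_model()].
#' @return An `lgct_model` of the ablated architecture.
#' @export
make_ablation_variant <- function(cfg, which, montage = NULL) {
  key <- gsub("[^a-z]", "", tolower(which))
  variant <- switch(key,
                    wotrans = "wo_trans",
                    wodiffhemi = "wo_diff_hemi",
                    wotdense = "wo_tdense",
                    stop("unknown ablation variant: ", which))
  cfg2 <- do.call(model_config, c(
    list(n_channels = cfg$n_channels, n_samples = cfg$n_samples,
         n_classes = cfg$n_classes, temporal = cfg$temporal,
         n_heads = cfg$n_heads, token_embed_dim = cfg$token_embed_dim,
         spatial = cfg$spatial, tdense = cfg$tdense,
         activation = cfg$activation, dropout_rate = cfg$dropout_rate,
         temporal_fusion = cfg$temporal_fusion, variant = variant,
         seed = cfg$seed)))
  build_model(cfg2, montage = montage)
}

#' Count trainable parameters
#'
#' Sums the lengths of all trainable arrays (batch-norm scale/shift included;
#' batch-norm running statistics are buffers, not parameters, and are
#' excluded).
#'
#' @param model an `lgct_model`, or any named list of parameter arrays.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "lgct_model")) model$params else model
  sum(vapply(p, length, 1L))
}

# ---- forward / backward ----------------------------------------------------
# Band inputs are cubes (T, C, N). Caches are nested lists mirroring the
# forward structure.

temporal_fwd <- function(X, params, pfx, cfg, dm, buffers, training) {
  d <- dim(X)
  Tt <- d[1L]; C <- d[2L]; N <- d[3L]
  S <- C * N
  Xc <- array(X, dim = c(Tt, 1L, S))
  conv <- conv1d_fwd(Xc, params[[paste0(pfx, "tconv.W")]],
                     params[[paste0(pfx, "tconv.b")]])
  cache <- list(Xc = Xc, Tt = Tt, C = C, N = N)
  if (dm$has_trans) {
    xtok <- matrix(as.vector(X), ncol = 1L)
    lift <- linear_fwd(xtok, params[[paste0(pfx, "lift.W")]],
                       params[[paste0(pfx, "lift.b")]])
    pe <- positional_encoding(Tt, dm$d)
    Z <- lift$out + pe[rep(seq_len(Tt), times = S), , drop = FALSE]
    enc <- enc_fwd(Z, Tt, params, paste0(pfx, "enc."), cfg$n_heads,
                   dm$d_k, dm$d_v, dm$half_local, cfg$activation,
                   cfg$dropout_rate, training)
    proj <- linear_fwd(enc$out, params[[paste0(pfx, "tproj.W")]],
                       params[[paste0(pfx, "tproj.b")]])
    trans_cube <- tokmat_to_cube(proj$out, Tt, S)
    fused <- if (cfg$temporal_fusion == "add") conv + trans_cube
             else cube_bind(conv, trans_cube)
    cache$lift <- lift; cache$enc <- enc; cache$proj <- proj
  } else {
    fused <- conv
  }
  bn <- bn_cube_fwd(fused, params[[paste0(pfx, "tbn.g")]],
                    params[[paste0(pfx, "tbn.b")]], buffers,
                    paste0(pfx, "tbn"), training)
  act <- act_fwd(bn$out, cfg$activation)
  pooled <- avgpool_fwd(act$out, cfg$temporal$pool_len,
                        cfg$temporal$pool_stride)
  cache$bn <- bn$cache; cache$act <- act$cache
  list(out = array(pooled, dim = c(dm$T1, dm$Fb, C, N)), cache = cache)
}

cube_bind <- function(a, b) {
  da <- dim(a)
  out <- array(0, dim = c(da[1L], da[2L] + dim(b)[2L], da[3L]))
  out[, seq_len(da[2L]), ] <- a
  out[, da[2L] + seq_len(dim(b)[2L]), ] <- b
  out
}

temporal_bwd <- function(dpool4, cache, params, pfx, cfg, dm, genv) {
  Tt <- cache$Tt; C <- cache$C; N <- cache$N
  S <- C * N
  dpool <- array(dpool4, dim = c(dm$T1, dm$Fb, S))
  dact <- avgpool_bwd(dpool, Tt, cfg$temporal$pool_len,
                      cfg$temporal$pool_stride)
  dbn_in <- act_bwd(dact, cache$act)
  bnb <- bn_cube_bwd(dbn_in, cache$bn)
  grad_acc(genv, paste0(pfx, "tbn.g"), bnb$dg)
  grad_acc(genv, paste0(pfx, "tbn.b"), bnb$db)
  dfused <- bnb$dX
  nf <- cfg$temporal$n_filters
  if (dm$has_trans) {
    if (cfg$temporal_fusion == "add") {
      dconv <- dfused; dtrans <- dfused
    } else {
      dconv <- dfused[, seq_len(nf), , drop = FALSE]
      dtrans <- dfused[, nf + seq_len(nf), , drop = FALSE]
    }
    dproj <- cube_to_tokmat(dtrans)
    pb <- linear_bwd(dproj, cache$proj$cache,
                     params[[paste0(pfx, "tproj.W")]])
    grad_acc(genv, paste0(pfx, "tproj.W"), pb$dW)
    grad_acc(genv, paste0(pfx, "tproj.b"), pb$db)
    dZ <- enc_bwd(pb$dX, cache$enc$cache, params, paste0(pfx, "enc."), genv)
    lb <- linear_bwd(dZ, cache$lift$cache, params[[paste0(pfx, "lift.W")]])
    grad_acc(genv, paste0(pfx, "lift.W"), lb$dW)
    grad_acc(genv, paste0(pfx, "lift.b"), lb$db)
  } else {
    dconv <- dfused
  }
  cb <- conv1d_bwd(dconv, cache$Xc, params[[paste0(pfx, "tconv.W")]])
  grad_acc(genv, paste0(pfx, "tconv.W"), cb$dW)
  grad_acc(genv, paste0(pfx, "tconv.b"), cb$db)
  invisible(NULL)
}

spatial_fwd <- function(A4, params, pfx, cfg, dm, montage, buffers, training) {
  d <- dim(A4)
  T1 <- d[1L]; Fb <- d[2L]; C <- d[3L]; N <- d[4L]
  flatten <- function(arr) {
    da <- dim(arr)
    matrix(aperm(arr, c(1L, 4L, 3L, 2L)), nrow = da[1L] * da[4L])
  }
  M_all <- flatten(A4)
  z1 <- linear_fwd(M_all, params[[paste0(pfx, "sp_all.W")]],
                   params[[paste0(pfx, "sp_all.b")]])
  cache <- list(T1 = T1, Fb = Fb, C = C, N = N, z1 = z1)
  if (dm$has_hemi) {
    ML <- flatten(A4[, , montage$left_idx, , drop = FALSE])
    MR <- flatten(A4[, , montage$right_idx, , drop = FALSE])
    zl <- linear_fwd(ML, params[[paste0(pfx, "sp_l.W")]],
                     params[[paste0(pfx, "sp_l.b")]])
    zr <- linear_fwd(MR, params[[paste0(pfx, "sp_r.W")]],
                     params[[paste0(pfx, "sp_r.b")]])
    Zcat <- cbind(z1$out, zl$out - zr$out)
    cache$zl <- zl; cache$zr <- zr
  } else {
    Zcat <- z1$out
  }
  bn <- bn_fwd(Zcat, params[[paste0(pfx, "sbn.g")]],
               params[[paste0(pfx, "sbn.b")]], buffers,
               paste0(pfx, "sbn"), training)
  act <- act_fwd(bn$out, cfg$activation)
  cache$bn <- bn$cache; cache$act <- act$cache
  list(out = tokmat_to_cube(act$out, T1, N), cache = cache)
}

spatial_bwd <- function(dU0, cache, params, pfx, cfg, dm, montage, genv) {
  S <- cfg$spatial$n_filters_per_path
  dZs <- cube_to_tokmat(dU0)
  dbn_in <- act_bwd(dZs, cache$act)
  bnb <- bn_bwd(dbn_in, cache$bn)
  grad_acc(genv, paste0(pfx, "sbn.g"), bnb$dg)
  grad_acc(genv, paste0(pfx, "sbn.b"), bnb$db)
  dZcat <- bnb$dX
  dz1 <- dZcat[, seq_len(S), drop = FALSE]
  b1 <- linear_bwd(dz1, cache$z1$cache, params[[paste0(pfx, "sp_all.W")]])
  grad_acc(genv, paste0(pfx, "sp_all.W"), b1$dW)
  grad_acc(genv, paste0(pfx, "sp_all.b"), b1$db)
  unflatten <- function(M, C) {
    aperm(array(M, dim = c(cache$T1, cache$N, C, cache$Fb)), c(1L, 4L, 3L, 2L))
  }
  dA4 <- unflatten(b1$dX, cache$C)
  if (dm$has_hemi) {
    ddiff <- dZcat[, S + seq_len(S), drop = FALSE]
    bl <- linear_bwd(ddiff, cache$zl$cache, params[[paste0(pfx, "sp_l.W")]])
    br <- linear_bwd(-ddiff, cache$zr$cache, params[[paste0(pfx, "sp_r.W")]])
    grad_acc(genv, paste0(pfx, "sp_l.W"), bl$dW)
    grad_acc(genv, paste0(pfx, "sp_l.b"), bl$db)
    grad_acc(genv, paste0(pfx, "sp_r.W"), br$dW)
    grad_acc(genv, paste0(pfx, "sp_r.b"), br$db)
    nh <- length(montage$left_idx)
    dA4[, , montage$left_idx, ] <- dA4[, , montage$left_idx, , drop = FALSE] +
      unflatten(bl$dX, nh)
    dA4[, , montage$right_idx, ] <- dA4[, , montage$right_idx, , drop = FALSE] +
      unflatten(br$dX, nh)
  }
  dA4
}

tdense_fwd <- function(U0, params, pfx, cfg, dm, buffers, training) {
  d <- dim(U0)
  T1 <- d[1L]; N <- d[3L]
  cache <- list(T1 = T1, N = N)
  layer_outs <- list()
  if (cfg$variant == "wo_tdense") {
    x <- U0
    cache$plain <- vector("list", dm$L)
    for (l in seq_len(dm$L)) {
      key <- sprintf("%std_plain%d", pfx, l)
      cv <- conv1d_fwd(x, params[[paste0(key, ".W")]],
                       params[[paste0(key, ".b")]])
      bn <- bn_cube_fwd(cv, params[[paste0(key, "_bn.g")]],
                        params[[paste0(key, "_bn.b")]], buffers,
                        paste0(key, "_bn"), training)
      ac <- act_fwd(bn$out, cfg$activation)
      dr <- dropout_fwd(ac$out, cfg$dropout_rate, training)
      cache$plain[[l]] <- list(x = x, bn = bn$cache, act = ac$cache,
                               dr = dr$cache)
      x <- dr$out
    }
    unit_out <- x
  } else {
    cnn_in <- list(U0)
    cache$cnn <- vector("list", dm$L)
    for (l in seq_len(dm$L)) {
      Dl <- do.call(cube_bind_all, cnn_in)
      key <- sprintf("%std_cnn%d", pfx, l)
      cv <- conv1d_fwd(Dl, params[[paste0(key, ".W")]],
                       params[[paste0(key, ".b")]])
      bn <- bn_cube_fwd(cv, params[[paste0(key, "_bn.g")]],
                        params[[paste0(key, "_bn.b")]], buffers,
                        paste0(key, "_bn"), training)
      ac <- act_fwd(bn$out, cfg$activation)
      dr <- dropout_fwd(ac$out, cfg$dropout_rate, training)
      cache$cnn[[l]] <- list(Dl = Dl, bn = bn$cache, act = ac$cache,
                             dr = dr$cache)
      cnn_in <- c(cnn_in, list(dr$out))
    }
    layer_outs <- cnn_in[-1L]
    if (dm$has_trans) {
      tr_in <- list(U0)
      cache$tr <- vector("list", dm$L)
      for (l in seq_len(dm$L)) {
        Dl <- do.call(cube_bind_all, tr_in)
        w_l <- dim(Dl)[2L]
        key <- sprintf("%std_tr%d", pfx, l)
        M <- cube_to_tokmat(Dl)
        pe <- positional_encoding(T1, w_l)
        Z <- M + pe[rep(seq_len(T1), times = N), , drop = FALSE]
        enc <- enc_fwd(Z, T1, params, paste0(key, "."), cfg$n_heads,
                       w_l %/% cfg$n_heads, w_l %/% cfg$n_heads, T1 - 1L,
                       cfg$activation, cfg$dropout_rate, training)
        proj <- linear_fwd(enc$out, params[[paste0(key, "_proj.W")]],
                           params[[paste0(key, "_proj.b")]])
        bn <- bn_fwd(proj$out, params[[paste0(key, "_bn.g")]],
                     params[[paste0(key, "_bn.b")]], buffers,
                     paste0(key, "_bn"), training)
        ac <- act_fwd(bn$out, cfg$activation)
        dr <- dropout_fwd(ac$out, cfg$dropout_rate, training)
        out_cube <- tokmat_to_cube(dr$out, T1, N)
        cache$tr[[l]] <- list(enc = enc$cache, proj = proj$cache,
                              bn = bn$cache, act = ac$cache, dr = dr$cache,
                              w_l = w_l)
        tr_in <- c(tr_in, list(out_cube))
      }
      layer_outs <- c(layer_outs, tr_in[-1L])
    }
    unit_out <- do.call(cube_bind_all, layer_outs)
  }
  red <- conv1d_fwd(unit_out, params[[paste0(pfx, "td_red.W")]],
                    params[[paste0(pfx, "td_red.b")]])
  bnr <- bn_cube_fwd(red, params[[paste0(pfx, "td_red_bn.g")]],
                     params[[paste0(pfx, "td_red_bn.b")]], buffers,
                     paste0(pfx, "td_red_bn"), training)
  acr <- act_fwd(bnr$out, cfg$activation)
  cache$unit_out <- unit_out; cache$bnr <- bnr$cache; cache$acr <- acr$cache
  list(out = acr$out, unit_out = unit_out, cache = cache)
}

cube_bind_all <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L) return(parts[[1L]])
  Reduce(cube_bind, parts)
}

tdense_bwd <- function(dout, cache, params, pfx, cfg, dm, genv) {
  dbnr_in <- act_bwd(dout, cache$acr)
  bnb <- bn_cube_bwd(dbnr_in, cache$bnr)
  grad_acc(genv, paste0(pfx, "td_red_bn.g"), bnb$dg)
  grad_acc(genv, paste0(pfx, "td_red_bn.b"), bnb$db)
  rb <- conv1d_bwd(bnb$dX, cache$unit_out, params[[paste0(pfx, "td_red.W")]])
  grad_acc(genv, paste0(pfx, "td_red.W"), rb$dW)
  grad_acc(genv, paste0(pfx, "td_red.b"), rb$db)
  dunit <- rb$dX
  T1 <- cache$T1; N <- cache$N
  g <- dm$g; K0 <- dm$K0
  if (cfg$variant == "wo_tdense") {
    dx <- dunit
    for (l in rev(seq_len(dm$L))) {
      key <- sprintf("%std_plain%d", pfx, l)
      lc <- cache$plain[[l]]
      dac <- dropout_bwd(dx, lc$dr)
      dbn_in <- act_bwd(dac, lc$act)
      bb <- bn_cube_bwd(dbn_in, lc$bn)
      grad_acc(genv, paste0(key, "_bn.g"), bb$dg)
      grad_acc(genv, paste0(key, "_bn.b"), bb$db)
      cb <- conv1d_bwd(bb$dX, lc$x, params[[paste0(key, ".W")]])
      grad_acc(genv, paste0(key, ".W"), cb$dW)
      grad_acc(genv, paste0(key, ".b"), cb$db)
      dx <- cb$dX
    }
    return(dx)
  }
  # split unit grad into the concatenated layer outputs
  slices <- list()
  off <- 0L
  for (l in seq_len(dm$L)) {
    slices[[sprintf("cnn%d", l)]] <- dunit[, off + seq_len(g), , drop = FALSE]
    off <- off + g
  }
  if (dm$has_trans) {
    for (l in seq_len(dm$L)) {
      slices[[sprintf("tr%d", l)]] <- dunit[, off + seq_len(g), , drop = FALSE]
      off <- off + g
    }
  }
  dU0 <- array(0, dim = c(T1, K0, N))
  # dense inputs: grads flowing into layer l's output from later layers
  dcnn_out <- slices[paste0("cnn", seq_len(dm$L))]
  dtr_out <- if (dm$has_trans) slices[paste0("tr", seq_len(dm$L))] else NULL
  for (l in rev(seq_len(dm$L))) {
    key <- sprintf("%std_cnn%d", pfx, l)
    lc <- cache$cnn[[l]]
    dac <- dropout_bwd(dcnn_out[[l]], lc$dr)
    dbn_in <- act_bwd(dac, lc$act)
    bb <- bn_cube_bwd(dbn_in, lc$bn)
    grad_acc(genv, paste0(key, "_bn.g"), bb$dg)
    grad_acc(genv, paste0(key, "_bn.b"), bb$db)
    cb <- conv1d_bwd(bb$dX, lc$Dl, params[[paste0(key, ".W")]])
    grad_acc(genv, paste0(key, ".W"), cb$dW)
    grad_acc(genv, paste0(key, ".b"), cb$db)
    # scatter dDl back: columns [1..K0] -> U0, then earlier cnn outputs
    dU0 <- dU0 + cb$dX[, seq_len(K0), , drop = FALSE]
    if (l > 1L) {
      for (j in seq_len(l - 1L)) {
        cols <- K0 + (j - 1L) * g + seq_len(g)
        dcnn_out[[j]] <- dcnn_out[[j]] + cb$dX[, cols, , drop = FALSE]
      }
    }
  }
  if (dm$has_trans) {
    for (l in rev(seq_len(dm$L))) {
      key <- sprintf("%std_tr%d", pfx, l)
      lc <- cache$tr[[l]]
      dM_out <- cube_to_tokmat(dtr_out[[l]])
      dac <- dropout_bwd(dM_out, lc$dr)
      dbn_in <- act_bwd(dac, lc$act)
      bb <- bn_bwd(dbn_in, lc$bn)
      grad_acc(genv, paste0(key, "_bn.g"), bb$dg)
      grad_acc(genv, paste0(key, "_bn.b"), bb$db)
      pb <- linear_bwd(bb$dX, lc$proj, params[[paste0(key, "_proj.W")]])
      grad_acc(genv, paste0(key, "_proj.W"), pb$dW)
      grad_acc(genv, paste0(key, "_proj.b"), pb$db)
      dZ <- enc_bwd(pb$dX, lc$enc, params, paste0(key, "."), genv)
      dDl <- tokmat_to_cube(dZ, T1, N)
      dU0 <- dU0 + dDl[, seq_len(K0), , drop = FALSE]
      if (l > 1L) {
        for (j in seq_len(l - 1L)) {
          cols <- K0 + (j - 1L) * g + seq_len(g)
          dtr_out[[j]] <- dtr_out[[j]] + dDl[, cols, , drop = FALSE]
        }
      }
    }
  }
  dU0
}

# full forward: bands is a list of n_bands cubes (T, C, N)
model_forward_core <- function(model, bands, training = FALSE,
                               keep_cache = FALSE) {
  cfg <- model$cfg
  dm <- model_dims(cfg)
  N <- dim(bands[[1L]])[3L]
  feats <- vector("list", cfg$n_bands)
  caches <- if (keep_cache) vector("list", cfg$n_bands) else NULL
  for (b in seq_len(cfg$n_bands)) {
    pfx <- sprintf("b%d.", b)
    tb <- temporal_fwd(bands[[b]], model$params, pfx, cfg, dm,
                       model$buffers, training)
    sb <- spatial_fwd(tb$out, model$params, pfx, cfg, dm, model$montage,
                      model$buffers, training)
    db <- tdense_fwd(sb$out, model$params, pfx, cfg, dm, model$buffers,
                     training)
    feats[[b]] <- matrix(db$out, nrow = dm$T1 * dm$R, ncol = N)
    if (keep_cache)
      caches[[b]] <- list(temporal = tb$cache, spatial = sb$cache,
                          tdense = db$cache)
  }
  feat <- t(do.call(rbind, feats))                 # N x head_in
  drop <- dropout_fwd(feat, cfg$dropout_rate, training)
  head <- linear_fwd(drop$out, model$params[["head.W"]],
                     model$params[["head.b"]])
  logits <- head$out
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits,
       cache = if (keep_cache) list(bands = caches, drop = drop$cache,
                                    head = head$cache, N = N, dm = dm)
               else NULL)
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

# backward from dlogits; fills genv with parameter gradients
model_backward_core <- function(model, dlogits, cache, genv) {
  cfg <- model$cfg
  dm <- cache$dm
  hb <- linear_bwd(dlogits, cache$head, model$params[["head.W"]])
  grad_acc(genv, "head.W", hb$dW)
  grad_acc(genv, "head.b", hb$db)
  dfeat <- dropout_bwd(hb$dX, cache$drop)
  per_band <- dm$T1 * dm$R
  for (b in seq_len(cfg$n_bands)) {
    pfx <- sprintf("b%d.", b)
    cols <- (b - 1L) * per_band + seq_len(per_band)
    dred <- array(t(dfeat[, cols, drop = FALSE]),
                  dim = c(dm$T1, dm$R, cache$N))
    dU0 <- tdense_bwd(dred, cache$bands[[b]]$tdense, model$params, pfx,
                      cfg, dm, genv)
    dA4 <- spatial_bwd(dU0, cache$bands[[b]]$spatial, model$params, pfx,
                       cfg, dm, model$montage, genv)
    temporal_bwd(dA4, cache$bands[[b]]$temporal, model$params, pfx, cfg,
                 dm, genv)
  }
  invisible(NULL)
}

# ---- exported block operations (evaluation-mode, FeatureMap orientation) ---

bands_from_input <- function(x) {
  # accepts lgct_multiband, lgct_epochs, or trials x channels x samples array
  if (inherits(x, "lgct_multiband"))
    return(lapply(x$epochs, function(e) aperm(e$data, c(3L, 2L, 1L))))
  if (inherits(x, "lgct_epochs")) return(list(aperm(x$data, c(3L, 2L, 1L))))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  list(aperm(x, c(3L, 2L, 1L)))
}

#' Temporal block forward pass
#'
#' Runs one band through the temporal block (1-D CNN path plus, unless
#' ablated, the local-transformer path; fused, batch-normalized, activated and
#' mean-pooled). Evaluation mode (no dropout).
#'
#' @param x one band: an `lgct_epochs` or `trials x channels x samples` array.
#' @param model an `lgct_model`.
#' @param band which band branch's weights to use (1-3).
#' @return A feature map array `trials x channels x filters x time`.
#' @export
temporal_block <- function(x, model, band = 1L) {
  X <- bands_from_input(x)[[1L]]
  dm <- model_dims(model$cfg)
  out <- temporal_fwd(X, model$params, sprintf("b%d.", band), model$cfg, dm,
                      model$buffers, training = FALSE)$out
  aperm(out, c(4L, 3L, 2L, 1L))
}

#' Spatial block forward pass
#'
#' Applies the all-channel and (unless ablated) hemisphere-difference spatial
#' filters to a temporal feature map. Evaluation mode.
#'
#' @param f a `trials x channels x filters x time` array as returned by
#'   [temporal_block()].
#' @param model an `lgct_model` (supplies weights and montage).
#' @param band branch index.
#' @return A feature map array `trials x feature-channels x time`.
#' @export
spatial_block <- function(f, model, band = 1L) {
  A4 <- aperm(f, c(4L, 3L, 2L, 1L))
  dm <- model_dims(model$cfg)
  out <- spatial_fwd(A4, model$params, sprintf("b%d.", band), model$cfg, dm,
                     model$montage, model$buffers, training = FALSE)$out
  aperm(out, c(3L, 2L, 1L))
}

#' T-Dense unit and block forward passes
#'
#' `tdense_unit` runs the densely connected CNN + global-transformer unit;
#' `tdense_block` additionally applies the dimension-reducing 1-D convolution.
#' Evaluation mode.
#'
#' @param f a `trials x feature-channels x time` array as returned by
#'   [spatial_block()].
#' @param model an `lgct_model`.
#' @param band branch index.
#' @return A `trials x feature-channels x time` array.
#' @export
tdense_unit <- function(f, model, band = 1L) {
  U0 <- aperm(f, c(3L, 2L, 1L))
  dm <- model_dims(model$cfg)
  r <- tdense_fwd(U0, model$params, sprintf("b%d.", band), model$cfg, dm,
                  model$buffers, training = FALSE)
  aperm(r$unit_out, c(3L, 2L, 1L))
}

#' @rdname tdense_unit
#' @export
tdense_block <- function(f, model, band = 1L) {
  U0 <- aperm(f, c(3L, 2L, 1L))
  dm <- model_dims(model$cfg)
  r <- tdense_fwd(U0, model$params, sprintf("b%d.", band), model$cfg, dm,
                  model$buffers, training = FALSE)
  aperm(r$out, c(3L, 2L, 1L))
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds `config.json` (the full model configuration
#' and montage), `params.json` (array names, shapes and byte offsets) and
#' `params.bin` (all parameter and buffer arrays concatenated as little-endian
#' float64). `load_model(save_model(m))` reproduces forward outputs
#' bit-for-bit; double precision is stored for exactly that reason.
#'
#' @param model an `lgct_model`.
#' @param path checkpoint directory (created if missing).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `lgct_model`.
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$cfg)
  mont <- if (is.null(model$montage)) NULL else model$montage$channel_names
  jsonlite::write_json(list(config = cfg, montage = mont),
                       file.path(path, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  bufs <- as.list(model$buffers)
  arrays <- c(model$params, bufs)
  index <- list()
  con <- file(file.path(path, "params.bin"), "wb")
  on.exit(close(con))
  offset <- 0L
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    index[[length(index) + 1L]] <-
      list(name = nm, dim = as.integer(dim2(a)),
           offset = offset, trainable = nm %in% names(model$params))
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
    offset <- offset + 8L * length(a)
  }
  jsonlite::write_json(index, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "config.json"),
                              simplifyVector = TRUE)
  cfgl <- meta$config
  montage <- if (!is.null(meta$montage)) make_montage(meta$montage) else NULL
  cfg <- model_config(cfgl$n_channels, cfgl$n_samples, cfgl$n_classes,
                      temporal = as.list(cfgl$temporal),
                      n_heads = cfgl$n_heads,
                      token_embed_dim = cfgl$token_embed_dim,
                      spatial = as.list(cfgl$spatial),
                      tdense = as.list(cfgl$tdense),
                      activation = cfgl$activation,
                      dropout_rate = cfgl$dropout_rate,
                      temporal_fusion = cfgl$temporal_fusion,
                      variant = cfgl$variant, seed = cfgl$seed)
  model <- build_model(cfg, montage = montage)
  index <- jsonlite::read_json(file.path(path, "params.json"),
                               simplifyVector = FALSE)
  con <- file(file.path(path, "params.bin"), "rb")
  on.exit(close(con))
  for (entry in index) {
    n <- prod(unlist(entry$dim))
    vals <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
    a <- if (length(entry$dim) > 1L)
      array(vals, dim = unlist(entry$dim)) else vals
    if (isTRUE(entry$trainable)) {
      if (!entry$name %in% names(model$params))
        stop("checkpoint parameter not in architecture: ", entry$name)
      model$params[[entry$name]] <- a
    } else {
      model$buffers[[entry$name]] <- a
    }
  }
  model
}

# deep copy including buffer snapshot (buffers are an environment)
snapshot_model <- function(model) {
  m <- model
  b <- new.env(parent = emptyenv())
  for (nm in ls(model$buffers)) b[[nm]] <- model$buffers[[nm]]
  m$buffers <- b
  m
}
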