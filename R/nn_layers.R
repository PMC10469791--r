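# Internal neural-network building blocks. Forward functions return
# list(out, cache); backward functions take the upstream gradient plus the
# cache and return gradients w.r.t. inputs and parameters. All trainable
# parameters live in a flat named list; gradients are accumulated into an
# environment keyed by parameter name.

# ---- tensor layout helpers -------------------------------------------------
# feature maps: cube (T, channels, N); token matrices: (T * n_seq) x d with
# rows ordered position-fastest within each sequence.

cube_to_tokmat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}

tokmat_to_cube <- function(M, Tt, n_seq) {
  aperm(array(M, dim = c(Tt, n_seq, ncol(M))), c(1L, 3L, 2L))
}

# ---- initialization --------------------------------------------------------

glorot <- function(dims) {
  fan <- if (length(dims) == 2L) c(dims[1L], dims[2L])
         else c(dims[1L] * dims[2L], dims[1L] * dims[3L])  # conv (K, Cin, Cout)
  lim <- sqrt(6 / sum(fan))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- activations -----------------------------------------------------------

act_fwd <- function(x, kind) {
  if (kind == "elu") {
    out <- elu_fwd_vec(x)
    dim(out) <- dim2(x)
  } else if (kind == "relu") {
    out <- x
    out[x < 0] <- 0
  } else stop("unsupported activation: ", kind)
  list(out = out, cache = list(x = x, out = out, kind = kind))
}

act_bwd <- function(dout, cache) {
  if (cache$kind == "elu") {
    g <- elu_bwd_vec(dout, cache$x, cache$out)
    dim(g) <- dim2(dout)
    g
  } else {
    g <- dout
    g[cache$x < 0] <- 0
    g
  }
}

# ---- dropout (inverted, seeded via the R RNG) ------------------------------

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim = dim2(x)) / (1 - rate)
  list(out = x * keep, cache = keep)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- linear ----------------------------------------------------------------

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}

linear_bwd <- function(dout, X, W) {
  list(dX = dout %*% t(W), dW = crossprod(X, dout), db = colSums(dout))
}

# ---- layer normalization (per row) -----------------------------------------

ln_fwd <- function(X, g, b, eps = 1e-5) {
  r <- ln_fwd_cpp(X, g, b, eps)
  list(out = r$out, cache = list(xhat = r$xhat, istd = r$istd, g = g))
}

ln_bwd <- function(dout, cache) {
  r <- ln_bwd_cpp(dout, cache$xhat, cache$istd, cache$g)
  list(dX = r$dX, dg = as.vector(r$dg), db = as.vector(r$db))
}

# ---- batch normalization (per column of an examples x features matrix) -----

bn_fwd <- function(X, g, b, buffers, key, training, momentum = 0.1,
                   eps = 1e-5) {
  m <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    buffers[[paste0(key, ".rm")]] <-
      (1 - momentum) * buffer_get(buffers, key, ".rm", mu) + momentum * mu
    buffers[[paste0(key, ".rv")]] <-
      (1 - momentum) * buffer_get(buffers, key, ".rv", v) + momentum * v
  } else {
    mu <- buffer_get(buffers, key, ".rm", numeric(ncol(X)))
    v <- buffer_get(buffers, key, ".rv", rep(1, ncol(X)))
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (X - rep(mu, each = m)) * rep(istd, each = m)
  out <- xhat * rep(g, each = m) + rep(b, each = m)
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g,
                               training = training))
}

buffer_get <- function(buffers, key, suffix, default) {
  val <- buffers[[paste0(key, suffix)]]
  if (is.null(val)) default else val
}

bn_bwd <- function(dout, cache) {
  m <- nrow(dout)
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * rep(cache$g, each = m)
  if (cache$training) {
    dX <- rep(cache$istd, each = m) *
      (dxhat - rep(colMeans(dxhat), each = m) -
         xhat * rep(colMeans(dxhat * xhat), each = m))
  } else {
    dX <- dxhat * rep(cache$istd, each = m)
  }
  list(dX = dX, dg = dg, db = db)
}

# BN over the channel axis of a (T, C, N) cube
bn_cube_fwd <- function(X, g, b, buffers, key, training) {
  d <- dim(X)
  r <- bn_fwd(cube_to_tokmat(X), g, b, buffers, key, training)
  list(out = tokmat_to_cube(r$out, d[1L], d[3L]), cache = r$cache)
}

bn_cube_bwd <- function(dout, cache) {
  d <- dim(dout)
  r <- bn_bwd(cube_to_tokmat(dout), cache)
  list(dX = tokmat_to_cube(r$dX, d[1L], d[3L]), dg = r$dg, db = r$db)
}

# ---- gradient accumulation -------------------------------------------------

grad_acc <- function(genv, name, value) {
  cur <- genv[[name]]
  genv[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

# ---- batched multi-head attention + encoder layer --------------------------
# Z: (T * n_seq) x d token matrix, positional encoding already added.
# Parameters under `pfx`: Wq, Wk (d x h*dk), Wv (d x h*dv), bq, bk, bv,
# Wo (h*dv x d), bo, ln1_g/b, W1 (d x 2d), b1, W2 (2d x d), b2, ln2_g/b.

enc_params_init <- function(d, n_heads, d_k, d_v) {
  list(
    Wq = glorot(c(d, n_heads * d_k)), bq = numeric(n_heads * d_k),
    Wk = glorot(c(d, n_heads * d_k)), bk = numeric(n_heads * d_k),
    Wv = glorot(c(d, n_heads * d_v)), bv = numeric(n_heads * d_v),
    Wo = glorot(c(n_heads * d_v, d)), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = glorot(c(d, 2L * d)), b1 = numeric(2L * d),
    W2 = glorot(c(2L * d, d)), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)
  )
}

enc_fwd <- function(Z, Tt, params, pfx, n_heads, d_k, d_v, half,
                    activation, dropout_rate, training) {
  p <- function(nm) params[[paste0(pfx, nm)]]
  n_seq <- nrow(Z) / Tt
  qm <- linear_fwd(Z, p("Wq"), p("bq"))
  km <- linear_fwd(Z, p("Wk"), p("bk"))
  vm <- linear_fwd(Z, p("Wv"), p("bv"))
  attn_count_bump(n_heads)
  mh <- mh_attn_fwd(qm$out, km$out, vm$out, as.integer(Tt),
                    as.integer(half), as.integer(n_heads))
  H <- mh$out
  om <- linear_fwd(H, p("Wo"), p("bo"))
  dr1 <- dropout_fwd(om$out, dropout_rate, training)
  l1 <- ln_fwd(Z + dr1$out, p("ln1_g"), p("ln1_b"))
  f1 <- linear_fwd(l1$out, p("W1"), p("b1"))
  a1 <- act_fwd(f1$out, activation)
  f2 <- linear_fwd(a1$out, p("W2"), p("b2"))
  dr2 <- dropout_fwd(f2$out, dropout_rate, training)
  l2 <- ln_fwd(l1$out + dr2$out, p("ln2_g"), p("ln2_b"))
  list(out = l2$out,
       cache = list(Z = Z, Tt = Tt, qm = qm, km = km, vm = vm,
                    P = mh$P, H = H, om = om, dr1 = dr1, l1 = l1,
                    f1 = f1, a1 = a1, f2 = f2, dr2 = dr2, l2 = l2,
                    half = half, n_heads = n_heads, d_k = d_k, d_v = d_v))
}

enc_bwd <- function(dout, cache, params, pfx, genv) {
  p <- function(nm) params[[paste0(pfx, nm)]]
  g <- function(nm, val) grad_acc(genv, paste0(pfx, nm), val)
  b2 <- ln_bwd(dout, cache$l2$cache)
  g("ln2_g", b2$dg); g("ln2_b", b2$db)
  dpre2 <- b2$dX                           # grad at l1$out + dr2$out
  dff2 <- dropout_bwd(dpre2, cache$dr2$cache)
  lb2 <- linear_bwd(dff2, cache$f2$cache, p("W2"))
  g("W2", lb2$dW); g("b2", lb2$db)
  da1 <- act_bwd(lb2$dX, cache$a1$cache)
  lb1 <- linear_bwd(da1, cache$f1$cache, p("W1"))
  g("W1", lb1$dW); g("b1", lb1$db)
  dl1out <- dpre2 + lb1$dX
  b1 <- ln_bwd(dl1out, cache$l1$cache)
  g("ln1_g", b1$dg); g("ln1_b", b1$db)
  dpre1 <- b1$dX                           # grad at Z + dr1$out
  dattn <- dropout_bwd(dpre1, cache$dr1$cache)
  lbo <- linear_bwd(dattn, cache$om$cache, p("Wo"))
  g("Wo", lbo$dW); g("bo", lbo$db)
  dH <- lbo$dX
  hb <- mh_attn_bwd(dH, cache$qm$out, cache$km$out, cache$vm$out, cache$P,
                    as.integer(cache$Tt), as.integer(cache$half),
                    as.integer(cache$n_heads))
  dqm <- hb$dQ; dkm <- hb$dK; dvm <- hb$dV
  lbq <- linear_bwd(dqm, cache$qm$cache, p("Wq"))
  lbk <- linear_bwd(dkm, cache$km$cache, p("Wk"))
  lbv <- linear_bwd(dvm, cache$vm$cache, p("Wv"))
  g("Wq", lbq$dW); g("bq", lbq$db)
  g("Wk", lbk$dW); g("bk", lbk$db)
  g("Wv", lbv$dW); g("bv", lbv$db)
  dpre1 + lbq$dX + lbk$dX + lbv$dX         # dZ
}

# ---- Adam ------------------------------------------------------------------

adam_state_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim2(p))),
       v = lapply(params, function(p) array(0, dim = dim2(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (length(gr) != length(params[[nm]]))
      stop("gradient shape mismatch for ", nm)
    gr <- array(as.numeric(gr), dim = dim2(params[[nm]]))
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
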