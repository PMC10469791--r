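#' Attention configuration
#'
#' @param n_heads number of parallel attention heads `h`.
#' @param d_model embedding width of the token stream.
#' @param d_k,d_v per-head query/key and value widths. Default `d_model /
#'   n_heads`.
#' @param mode `"local"` (banded window) or `"global"` (all keys).
#' @param window odd window length for local mode (keys within
#'   `(window-1)/2` positions of the query).
#' @return An object of class `lgct_attn_config`.
#' @export
attention_config <- function(n_heads = 2L, d_model = 16L,
                             d_k = d_model %/% n_heads,
                             d_v = d_model %/% n_heads,
                             mode = c("local", "global"), window = 25L) {
  mode <- match.arg(mode)
  stopifnot(n_heads >= 1L, d_model >= 1L, d_k >= 1L, d_v >= 1L)
  if (mode == "local") {
    if (window < 1L || window %% 2L == 0L)
      stop("local attention window must be an odd positive integer")
  }
  structure(list(n_heads = as.integer(n_heads), d_model = as.integer(d_model),
                 d_k = as.integer(d_k), d_v = as.integer(d_v),
                 mode = mode, window = as.integer(window)),
            class = "lgct_attn_config")
}

#' Banded mask for local (windowed) attention
#'
#' Query position `i` may attend to key position `j` iff
#' `|i - j| <= (window - 1) / 2`; the mask is symmetric and every row allows
#' at least the diagonal.
#'
#' @param seq_len sequence length.
#' @param window odd positive window length.
#' @return `seq_len x seq_len` logical matrix (`TRUE` = attention allowed).
#' @export
local_attention_mask <- function(seq_len, window) {
  stopifnot(seq_len >= 1L)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer (got ", window, ")")
  half <- (window - 1L) / 2L
  i <- matrix(seq_len(seq_len), seq_len, seq_len)
  abs(i - t(i)) <= half
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`, with optionally masked
#' (disallowed) query-key pairs receiving exactly zero weight. Softmax rows
#' are stabilized by max subtraction.
#'
#' @param Q `n x d_k` query matrix.
#' @param K `m x d_k` key matrix.
#' @param V `m x d_v` value matrix.
#' @param mask optional `n x m` logical matrix, `TRUE` where attention is
#'   allowed. A fully masked row is an error.
#' @param return_weights if `TRUE`, also return the attention weight matrix.
#' @return `n x d_v` output matrix, or a list `(output, weights)` when
#'   `return_weights = TRUE`.
#' @export
scaled_dot_product_attention <- function(Q, K, V, mask = NULL,
                                         return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  attn_count_bump()
  scores <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopifnot(nrow(mask) == nrow(Q), ncol(mask) == nrow(K))
    if (any(rowSums(mask) == 0L))
      stop("attention mask has a fully masked query row")
    scores[!mask] <- -Inf
  }
  w <- exp(scores - apply(scores, 1L, max))
  w[is.na(w)] <- 0        # -Inf - -Inf rows cannot occur (mask rows checked)
  w <- w / rowSums(w)
  out <- w %*% V
  if (return_weights) list(output = out, weights = w) else out
}

#' Multi-head attention (reference implementation)
#'
#' Each head applies its own learned projections to queries, keys and values,
#' runs scaled dot-product attention, and the concatenated head outputs are
#' projected by `W_o` (`h*d_v x d_model`).
#'
#' @param X `n x d_model` token matrix (self-attention: queries = keys =
#'   values = `X`).
#' @param cfg an [attention_config()].
#' @param params list with `Wq`, `Wk` (each a list of `n_heads` matrices
#'   `d_model x d_k`), `Wv` (list of `d_model x d_v`), and `Wo`
#'   (`n_heads*d_v x d_model`).
#' @param mask optional `n x n` logical mask.
#' @return `n x d_model` matrix.
#' @export
multi_head_attention <- function(X, cfg, params, mask = NULL) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == cfg$d_model)
  check_mha_params(cfg, params)
  heads <- lapply(seq_len(cfg$n_heads), function(i) {
    scaled_dot_product_attention(X %*% params$Wq[[i]],
                                 X %*% params$Wk[[i]],
                                 X %*% params$Wv[[i]], mask = mask)
  })
  do.call(cbind, heads) %*% params$Wo
}

check_mha_params <- function(cfg, params) {
  h <- cfg$n_heads
  for (nm in c("Wq", "Wk", "Wv")) {
    if (length(params[[nm]]) != h)
      stop(nm, " must be a list of ", h, " per-head projection matrices")
  }
  dk <- vapply(params$Wq, ncol, 1L)
  dv <- vapply(params$Wv, ncol, 1L)
  if (any(dk != cfg$d_k) || any(dv != cfg$d_v))
    stop("per-head projection widths do not match cfg (d_k=", cfg$d_k,
         ", d_v=", cfg$d_v, ")")
  if (nrow(params$Wo) != h * cfg$d_v || ncol(params$Wo) != cfg$d_model)
    stop("Wo must be (n_heads*d_v) x d_model = ",
         h * cfg$d_v, " x ", cfg$d_model)
  invisible(TRUE)
}

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))` and
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))` for 0-based positions
#' `pos = 0, ..., seq_len-1` and dimension pairs `i = 0, ..., d/2-1`. The
#' caller adds the encoding to its token embeddings.
#'
#' @param seq_len number of positions.
#' @param d even embedding dimension.
#' @return `seq_len x d` matrix.
#' @export
positional_encoding <- function(seq_len, d) {
  stopifnot(seq_len >= 1L)
  if (d %% 2L != 0L) stop("positional encoding dimension d must be even")
  pos <- seq_len(seq_len) - 1
  i <- seq_len(d / 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d))
  pe <- matrix(0, seq_len, d)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Transformer encoder layer (reference implementation)
#'
#' The canonical post-norm encoder layer: multi-head self-attention (masked in
#' local mode with the banded window) with residual connection and layer
#' normalization, then a position-wise feed-forward network (width
#' `2*d_model`, ELU) with residual and layer normalization. Deterministic:
#' this reference path applies no dropout.
#'
#' @param X `n x d_model` token matrix (positional encoding, if wanted, is
#'   added by the caller).
#' @param cfg an [attention_config()]; `cfg$mode == "local"` applies
#'   [local_attention_mask()] with `cfg$window`.
#' @param params list with the [multi_head_attention()] params plus `ln1_g`,
#'   `ln1_b`, `ln2_g`, `ln2_b` (length-`d_model` vectors) and `W1`
#'   (`d_model x 2 d_model`), `b1`, `W2` (`2 d_model x d_model`), `b2`.
#' @return `n x d_model` matrix.
#' @export
transformer_encoder_layer <- function(X, cfg, params) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), ncol(X) == cfg$d_model)
  mask <- if (cfg$mode == "local")
    local_attention_mask(nrow(X), cfg$window) else NULL
  a <- multi_head_attention(X, cfg, params, mask = mask)
  z1 <- layer_norm_ref(X + a, params$ln1_g, params$ln1_b)
  ff <- elu_ref(sweep(z1 %*% params$W1, 2L, params$b1, `+`)) %*% params$W2
  ff <- sweep(ff, 2L, params$b2, `+`)
  layer_norm_ref(z1 + ff, params$ln2_g, params$ln2_b)
}

layer_norm_ref <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sweep(xc / sqrt(v + eps), 2L, g, `*`) + rep(b, each = nrow(X))
}

elu_ref <- function(x) ifelse(x > 0, x, exp(x) - 1)

# ---- attention call counter (structural ablation probe) ----

attn_counter_env <- new.env(parent = emptyenv())
attn_counter_env$n <- 0L

attn_count_bump <- function(n = 1L) {
  attn_counter_env$n <- attn_counter_env$n + as.integer(n)
  invisible(NULL)
}

#' Attention call counter
#'
#' Every scaled dot-product attention evaluation (reference or engine path)
#' increments a package-global counter; useful to verify structurally that an
#' ablated model performs no attention computation.
#'
#' @return `attention_call_count()` returns the current count;
#'   `reset_attention_call_count()` zeroes it (invisibly).
#' @export
attention_call_count <- function() attn_counter_env$n

#' @rdname attention_call_count
#' @export
reset_attention_call_count <- function() {
  attn_counter_env$n <- 0L
  invisible(NULL)
}
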