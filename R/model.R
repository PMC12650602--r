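# Dual-branch beat classifier: residual CNN branch, Transformer encoder
# branch with sinusoidal positional encoding, per-dimension gated fusion,
# softmax classifier. This file holds the model configuration, parameter
# initialization, and a pure-R double-precision reference implementation of
# every building block; training and batched inference run through the
# single-precision C++ engine (src/engine.cpp), and parity between the two
# paths is tested.

#' Model configuration
#'
#' Architecture hyperparameters of the network. The convolutional branch
#' is fixed as: stem Conv1D 1->64 (kernel 7, stride 1, padding 3), then
#' three residual blocks (64->64 stride 1, 64->128 stride 2, 128->256
#' stride 1; two kernel-3 convolutions each, batch-norm + ReLU, skip
#' connection with a 1x1 convolution where shape changes), followed by
#' global average pooling to a 256-vector. The Transformer branch embeds
#' each sample to `d_model`, adds sinusoidal positional encoding, applies
#' `n_transformer_layers` post-norm encoder layers (`n_heads` heads, FFN
#' width `ffn_dim`, dropout `transformer_dropout`), and average-pools to a
#' `d_model`-vector.
#'
#' @param variant One of `"full"`, `"cnn_only"`, `"transformer_only"`,
#'   `"concat_no_gate"` (the ablation switches).
#' @param input_length Beat window length (188 samples).
#' @param d_model Transformer embedding width (128).
#' @param n_transformer_layers Number of encoder layers (2).
#' @param n_heads Attention heads (4); must divide `d_model`.
#' @param ffn_dim Feed-forward width (256).
#' @param transformer_dropout Dropout inside encoder layers (0.1).
#' @param fusion_dim Shared latent width H of the fusion module (256).
#' @param classifier_hidden Classifier hidden width (128).
#' @param classifier_dropout Classifier dropout (0.3).
#' @param n_classes Output classes (5).
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("full", "cnn_only", "transformer_only",
                                     "concat_no_gate"),
                         input_length = 188L, d_model = 128L,
                         n_transformer_layers = 2L, n_heads = 4L,
                         ffn_dim = 256L, transformer_dropout = 0.1,
                         fusion_dim = 256L, classifier_hidden = 128L,
                         classifier_dropout = 0.3, n_classes = 5L) {
  variant <- match.arg(variant)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  stopifnot(input_length > 0, d_model > 0, ffn_dim > 0, fusion_dim > 0,
            classifier_hidden > 0, n_classes > 0)
  structure(list(variant = variant, input_length = as.integer(input_length),
                 d_model = as.integer(d_model),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
                 transformer_dropout = transformer_dropout,
                 fusion_dim = as.integer(fusion_dim),
                 classifier_hidden = as.integer(classifier_hidden),
                 classifier_dropout = classifier_dropout,
                 n_classes = as.integer(n_classes),
                 cnn_out = 256L),
            class = "model_config")
}

# CNN branch structure: list of (C_in, C_out, stride) per residual block.
cnn_blocks <- function() {
  list(c(64L, 64L, 1L), c(64L, 128L, 2L), c(128L, 256L, 1L))
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i / d_model))` and entry
#' `(pos, 2i+1)` is `cos(pos / 10000^(2i / d_model))`, for `pos` in
#' `0..L-1` (rows) and `i` in `0..d_model/2-1`.
#'
#' @param L Sequence length (>= 1).
#' @param d_model Even embedding width.
#' @return Matrix `[L x d_model]`, all entries in `[-1, 1]`.
#' @export
positional_encoding <- function(L, d_model) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  stopifnot(L >= 1)
  pos <- 0:(L - 1)
  i <- 0:(d_model / 2 - 1)
  angle <- outer(pos, 10000^(2 * i / d_model), `/`)
  pe <- matrix(0, L, d_model)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, with the softmax taken over the key
#' axis, so every attention row sums to 1. `d_k` is taken from the column
#' count of `K`.
#'
#' @param Q,K,V Numeric matrices; `Q` and `K` share their inner dimension.
#' @return Matrix `[nrow(Q) x ncol(V)]`.
#' @export
attention <- function(Q, K, V) {
  if (!all(is.finite(Q), is.finite(K), is.finite(V))) {
    stop("attention inputs must be finite")
  }
  if (ncol(Q) != ncol(K)) stop("Q and K must share their inner dimension")
  s <- Q %*% t(K) / sqrt(ncol(K))
  p <- exp(s - apply(s, 1L, max))
  p <- p / rowSums(p)
  p %*% V
}

softmax_rows <- function(z) {
  p <- exp(z - apply(z, 1L, max))
  p / rowSums(p)
}

# ---- parameter initialization -------------------------------------------

he_mat <- function(nout, nin_eff, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin_eff)), nout, nin)

init_conv <- function(params, name, c_out, c_in, k) {
  params[[paste0(name, ".W")]] <- he_mat(c_out, c_in * k, c_in * k)
  params[[paste0(name, ".b")]] <- numeric(c_out)
  params
}

init_linear <- function(params, name, nout, nin) {
  params[[paste0(name, ".W")]] <- he_mat(nout, nin, nin)
  params[[paste0(name, ".b")]] <- numeric(nout)
  params
}

init_norm <- function(params, name, d) {
  params[[paste0(name, ".gamma")]] <- rep(1, d)
  params[[paste0(name, ".beta")]] <- numeric(d)
  params
}

needs_cnn <- function(variant) variant %in% c("full", "cnn_only", "concat_no_gate")
needs_transformer <- function(variant) variant %in% c("full", "transformer_only", "concat_no_gate")
needs_projection <- function(variant) variant %in% c("full", "concat_no_gate")

classifier_input_dim <- function(config) {
  switch(config$variant,
         full = config$fusion_dim,
         cnn_only = config$cnn_out,
         transformer_only = config$d_model,
         concat_no_gate = 2L * config$fusion_dim)
}

init_hctg_params <- function(config, seed = 1L) {
  with_seed(seed, {
    p <- list()
    s <- list()
    if (needs_cnn(config$variant)) {
      p <- init_conv(p, "stem", 64L, 1L, 7L)
      p <- init_norm(p, "stem.bn", 64L)
      s[["stem.bn.mean"]] <- numeric(64L); s[["stem.bn.var"]] <- rep(1, 64L)
      blocks <- cnn_blocks()
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]; nm <- paste0("res", bi)
        p <- init_conv(p, paste0(nm, ".conv1"), b[2], b[1], 3L)
        p <- init_norm(p, paste0(nm, ".bn1"), b[2])
        p <- init_conv(p, paste0(nm, ".conv2"), b[2], b[2], 3L)
        p <- init_norm(p, paste0(nm, ".bn2"), b[2])
        s[[paste0(nm, ".bn1.mean")]] <- numeric(b[2])
        s[[paste0(nm, ".bn1.var")]] <- rep(1, b[2])
        s[[paste0(nm, ".bn2.mean")]] <- numeric(b[2])
        s[[paste0(nm, ".bn2.var")]] <- rep(1, b[2])
        if (b[1] != b[2] || b[3] != 1L) {
          p <- init_conv(p, paste0(nm, ".down"), b[2], b[1], 1L)
        }
      }
    }
    if (needs_transformer(config$variant)) {
      p <- init_linear(p, "embed", config$d_model, 1L)
      for (li in seq_len(config$n_transformer_layers)) {
        nm <- paste0("tr", li)
        for (w in c("q", "k", "v", "o")) {
          p <- init_linear(p, paste0(nm, ".W", w), config$d_model, config$d_model)
        }
        p <- init_norm(p, paste0(nm, ".ln1"), config$d_model)
        p <- init_linear(p, paste0(nm, ".ffn1"), config$ffn_dim, config$d_model)
        p <- init_linear(p, paste0(nm, ".ffn2"), config$d_model, config$ffn_dim)
        p <- init_norm(p, paste0(nm, ".ln2"), config$d_model)
      }
    }
    if (needs_projection(config$variant)) {
      p <- init_linear(p, "fus.c", config$fusion_dim, config$cnn_out)
      p <- init_linear(p, "fus.t", config$fusion_dim, config$d_model)
    }
    if (config$variant == "full") {
      p <- init_linear(p, "fus.gate1", config$fusion_dim, 2L * config$fusion_dim)
      p <- init_linear(p, "fus.gate2", config$fusion_dim, config$fusion_dim)
    }
    p <- init_linear(p, "clf1", config$classifier_hidden, classifier_input_dim(config))
    p <- init_linear(p, "clf2", config$n_classes, config$classifier_hidden)
    list(params = p, state = s)
  })
}

#' Construct a beat-classification model
#'
#' Initializes all weights (fan-in-scaled Gaussian, seeded) for the chosen
#' architecture variant and precomputes the positional-encoding table.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `hctg_model` holding `config`, `params`
#'   (named list of weight matrices/vectors), `state` (batch-norm running
#'   statistics) and `pe` (positional encoding).
#' @export
hctg_model <- function(config = model_config(), seed = 1L) {
  ps <- init_hctg_params(config, seed)
  structure(list(config = config, params = ps$params, state = ps$state,
                 pe = positional_encoding(config$input_length, config$d_model),
                 classes = aami_classes(), seed = as.integer(seed)),
            class = "hctg_model")
}

#' @export
print.hctg_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<hctg_model> variant %s, %s parameters\n",
              x$config$variant, format(n_par, big.mark = ",")))
  invisible(x)
}

# ---- pure-R reference forward path --------------------------------------
# Batch activations are stored as [C x (B*T)] matrices, columns sample-major
# (sample 1's T columns first), matching the C++ engine layout.

# 1-D convolution over a batched channel matrix.
conv1d_batch <- function(x, B, T_in, W, b, stride = 1L, pad = 1L) {
  c_in <- nrow(x)
  k <- ncol(W) / c_in
  T_pad <- T_in + 2L * pad
  T_out <- (T_pad - k) %/% stride + 1L
  xp <- matrix(0, c_in, B * T_pad)
  src <- rep((0:(B - 1)) * T_in, each = T_in) + rep(seq_len(T_in), B)
  dst <- rep((0:(B - 1)) * T_pad, each = T_in) + rep(seq_len(T_in) + pad, B)
  xp[, dst] <- x[, src, drop = FALSE]
  y <- matrix(rep(b, B * T_out), nrow(W), B * T_out)
  base <- rep((0:(B - 1)) * T_pad, each = T_out) +
    rep(seq(1L, by = stride, length.out = T_out), B)
  for (j in seq_len(k)) {
    Wj <- W[, ((j - 1) * c_in + 1):(j * c_in), drop = FALSE]
    y <- y + Wj %*% xp[, base + (j - 1L), drop = FALSE]
  }
  list(y = y, T_out = T_out)
}

bn_eval <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  (x - mean) / sqrt(var + eps) * gamma + beta
}

bn_batch <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  (x - mu) / sqrt(v + eps) * gamma + beta
}

bn_apply <- function(x, params, state, name, training) {
  g <- params[[paste0(name, ".gamma")]]
  b <- params[[paste0(name, ".beta")]]
  if (training) bn_batch(x, g, b)
  else bn_eval(x, g, b, state[[paste0(name, ".mean")]],
               state[[paste0(name, ".var")]])
}

relu <- function(x) pmax(x, 0)

# Mean over the time axis: [C x B*T] -> [C x B]
pool_time <- function(x, B, T_len) {
  grp <- rep(seq_len(B), each = T_len)
  p <- t(rowsum(t(x), grp)) / T_len
  dimnames(p) <- NULL
  p
}

as_chan_mat <- function(x) {
  # [B x L] input matrix -> single-channel [1 x B*L] layout
  matrix(as.numeric(t(x)), nrow = 1L)
}

#' Forward pass of one residual block (reference path)
#'
#' Computes `ReLU(F(x) + skip(x))` where `F` is conv-BN-ReLU-conv-BN and
#' the skip path is the identity when shapes match, else a strided 1x1
#' convolution.
#'
#' @param model An [hctg_model()] whose variant includes the CNN branch.
#' @param x Array `[B, C_in, T]`.
#' @param block Block index 1..3.
#' @param training Use batch statistics in batch-norm?
#' @return Array `[B, C_out, ceil(T / stride)]`.
#' @export
residual_block_forward <- function(model, x, block, training = FALSE) {
  stopifnot(length(dim(x)) == 3L, block %in% 1:3)
  spec <- cnn_blocks()[[block]]
  B <- dim(x)[1]; C_in <- dim(x)[2]; T_in <- dim(x)[3]
  if (C_in != spec[1]) {
    stop(sprintf("residual block %d expects %d input channels, got %d",
                 block, spec[1], C_in))
  }
  xm <- matrix(aperm(x, c(2, 3, 1)), C_in, B * T_in)
  out <- res_block_mat(xm, B, T_in, model$params, model$state,
                       paste0("res", block), spec, training)
  aperm(array(out$y, c(spec[2], out$T_out, B)), c(3, 1, 2))
}

res_block_mat <- function(xm, B, T_in, params, state, nm, spec, training) {
  c1 <- conv1d_batch(xm, B, T_in, params[[paste0(nm, ".conv1.W")]],
                     params[[paste0(nm, ".conv1.b")]], stride = spec[3], pad = 1L)
  h <- relu(bn_apply(c1$y, params, state, paste0(nm, ".bn1"), training))
  c2 <- conv1d_batch(h, B, c1$T_out, params[[paste0(nm, ".conv2.W")]],
                     params[[paste0(nm, ".conv2.b")]], stride = 1L, pad = 1L)
  f <- bn_apply(c2$y, params, state, paste0(nm, ".bn2"), training)
  if (!is.null(params[[paste0(nm, ".down.W")]])) {
    d <- conv1d_batch(xm, B, T_in, params[[paste0(nm, ".down.W")]],
                      params[[paste0(nm, ".down.b")]], stride = spec[3], pad = 0L)
    skip <- d$y
  } else {
    skip <- xm
  }
  list(y = relu(f + skip), T_out = c2$T_out)
}

#' CNN branch forward (reference path)
#'
#' Stem convolution, three residual blocks, global average pooling over
#' time, producing a 256-dimensional morphology feature per beat.
#'
#' @param model An [hctg_model()].
#' @param x Matrix `[B x 188]` of normalized beats.
#' @param training Use batch statistics in batch-norm?
#' @param return_stages Also return every intermediate stage's dimensions?
#' @return Matrix `[B x 256]`, or a list with `features` and `stages`.
#' @export
cnn_branch_forward <- function(model, x, training = FALSE,
                               return_stages = FALSE) {
  L <- model$config$input_length
  if (ncol(x) != L) stop("expected input length ", L, ", got ", ncol(x))
  B <- nrow(x)
  p <- model$params; s <- model$state
  xm <- as_chan_mat(x)
  stem <- conv1d_batch(xm, B, L, p[["stem.W"]], p[["stem.b"]],
                       stride = 1L, pad = 3L)
  h <- relu(bn_apply(stem$y, p, s, "stem.bn", training))
  stages <- list(stem = c(B, 64L, stem$T_out))
  T_cur <- stem$T_out
  for (bi in 1:3) {
    spec <- cnn_blocks()[[bi]]
    out <- res_block_mat(h, B, T_cur, p, s, paste0("res", bi), spec, training)
    h <- out$y; T_cur <- out$T_out
    stages[[paste0("res", bi)]] <- c(B, spec[2], T_cur)
  }
  feat <- t(pool_time(h, B, T_cur))
  stages$pool <- dim(feat)
  if (return_stages) list(features = feat, stages = stages) else feat
}

layer_norm_cols <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  sweep((x - rep(mu, each = nrow(x))) /
          rep(sqrt(v + eps), each = nrow(x)), 1L, gamma, `*`) + beta
}

#' Transformer branch forward (reference path)
#'
#' Embeds each sample to `d_model`, adds sinusoidal positional encoding,
#' applies the stacked post-norm encoder layers (multi-head self-attention
#' and position-wise FFN, each followed by residual connection and layer
#' normalization), then average-pools over the sequence. Dropout is
#' inactive on this path (evaluation mode).
#'
#' @param model An [hctg_model()].
#' @param x Matrix `[B x 188]`.
#' @param attention_hook Optional replacement for the attention operation
#'   (test hook); a function `(Q, K, V) -> matrix`, e.g. `function(Q, K, V) V`
#'   for identity attention.
#' @return Matrix `[B x d_model]`.
#' @export
transformer_branch_forward <- function(model, x, attention_hook = NULL) {
  cfg <- model$config
  L <- cfg$input_length; d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  if (ncol(x) != L) stop("expected input length ", L, ", got ", ncol(x))
  B <- nrow(x)
  p <- model$params
  att <- attention_hook %||% attention
  # [d x B*L], columns sample-major
  xe <- p[["embed.W"]] %*% matrix(as.numeric(t(x)), 1L) +
    p[["embed.b"]]
  pe_t <- t(model$pe)                       # [d x L]
  xe <- xe + pe_t[, rep(seq_len(L), B), drop = FALSE]
  h <- xe
  for (li in seq_len(cfg$n_transformer_layers)) {
    nm <- paste0("tr", li)
    Q <- p[[paste0(nm, ".Wq.W")]] %*% h + p[[paste0(nm, ".Wq.b")]]
    K <- p[[paste0(nm, ".Wk.W")]] %*% h + p[[paste0(nm, ".Wk.b")]]
    V <- p[[paste0(nm, ".Wv.W")]] %*% h + p[[paste0(nm, ".Wv.b")]]
    O <- matrix(0, d, B * L)
    for (b in seq_len(B)) {
      cols <- ((b - 1) * L + 1):(b * L)
      for (hh in seq_len(H)) {
        rows <- ((hh - 1) * dk + 1):(hh * dk)
        O[rows, cols] <- t(att(t(Q[rows, cols]), t(K[rows, cols]),
                               t(V[rows, cols])))
      }
    }
    a <- p[[paste0(nm, ".Wo.W")]] %*% O + p[[paste0(nm, ".Wo.b")]]
    h <- layer_norm_cols(h + a, p[[paste0(nm, ".ln1.gamma")]],
                         p[[paste0(nm, ".ln1.beta")]])
    ff <- p[[paste0(nm, ".ffn2.W")]] %*%
      relu(p[[paste0(nm, ".ffn1.W")]] %*% h + p[[paste0(nm, ".ffn1.b")]]) +
      p[[paste0(nm, ".ffn2.b")]]
    h <- layer_norm_cols(h + ff, p[[paste0(nm, ".ln2.gamma")]],
                         p[[paste0(nm, ".ln2.beta")]])
  }
  t(pool_time(h, B, L))
}

#' Gated fusion of CNN and Transformer features
#'
#' Projects both branch features into the shared latent space
#' (`c_tilde = Wc c`, `t_tilde = Wt t`), computes the per-dimension gate
#' `g = sigmoid(MLP([c_tilde; t_tilde]))` (two fully connected layers,
#' 2H -> H -> H, ReLU between), and fuses
#' `f = g * c_tilde + (1 - g) * t_tilde`.
#'
#' @param model An [hctg_model()] with variant `"full"` (or
#'   `"concat_no_gate"`, in which case `g` is `NULL` and `f` is the
#'   concatenation).
#' @param c_feat Matrix `[B x 256]` from the CNN branch.
#' @param t_feat Matrix `[B x d_model]` from the Transformer branch.
#' @param g_override Optional fixed gate value(s) in `[0, 1]` (test hook).
#' @return List (`FusionState`) with `c`, `t`, `c_tilde`, `t_tilde`, `g`, `f`.
#' @export
gated_fusion <- function(model, c_feat, t_feat, g_override = NULL) {
  p <- model$params
  if (ncol(c_feat) != model$config$cnn_out ||
      ncol(t_feat) != model$config$d_model) {
    stop("gated_fusion: feature dimensions do not match the configuration")
  }
  ct <- t(p[["fus.c.W"]] %*% t(c_feat) + p[["fus.c.b"]])
  tt <- t(p[["fus.t.W"]] %*% t(t_feat) + p[["fus.t.b"]])
  if (model$config$variant == "concat_no_gate") {
    return(list(c = c_feat, t = t_feat, c_tilde = ct, t_tilde = tt,
                g = NULL, f = cbind(ct, tt)))
  }
  if (is.null(g_override)) {
    z <- relu(p[["fus.gate1.W"]] %*% t(cbind(ct, tt)) + p[["fus.gate1.b"]])
    g <- t(1 / (1 + exp(-(p[["fus.gate2.W"]] %*% z + p[["fus.gate2.b"]]))))
  } else {
    g <- matrix(g_override, nrow(ct), ncol(ct))
  }
  list(c = c_feat, t = t_feat, c_tilde = ct, t_tilde = tt, g = g,
       f = g * ct + (1 - g) * tt)
}

#' Softmax classification head
#'
#' Maps a fused feature vector through the hidden layer (ReLU) and the
#' output layer, then normalizes with softmax. Ties in the argmax are
#' broken toward the lowest class index.
#'
#' @param model An [hctg_model()].
#' @param f Matrix `[B x input_dim]` (or a single feature vector).
#' @return List with `probabilities` (`[B x 5]`, rows sum to 1) and
#'   `predicted_class` (factor over the five classes).
#' @export
classify <- function(model, f) {
  if (is.null(dim(f))) f <- matrix(f, 1L)
  if (!all(is.finite(f))) stop("classify: non-finite features")
  p <- model$params
  h <- relu(p[["clf1.W"]] %*% t(f) + p[["clf1.b"]])
  z <- t(p[["clf2.W"]] %*% h + p[["clf2.b"]])
  probs <- softmax_rows(z)
  colnames(probs) <- model$classes
  cls <- factor(model$classes[apply(probs, 1L, which.max)],
                levels = model$classes)
  list(probabilities = probs, predicted_class = cls)
}

# Full reference forward (evaluation mode); used for parity testing and
# small-batch inspection.
hctg_forward_ref <- function(model, x, g_override = NULL) {
  v <- model$config$variant
  c_feat <- if (needs_cnn(v)) cnn_branch_forward(model, x) else NULL
  t_feat <- if (needs_transformer(v)) transformer_branch_forward(model, x) else NULL
  if (v == "cnn_only") {
    feat <- c_feat; fus <- NULL
  } else if (v == "transformer_only") {
    feat <- t_feat; fus <- NULL
  } else {
    fus <- gated_fusion(model, c_feat, t_feat, g_override = g_override)
    feat <- fus$f
  }
  out <- classify(model, feat)
  list(probabilities = out$probabilities,
       predicted_class = out$predicted_class,
       c = c_feat, t = t_feat, fusion = fus)
}

#' Forward pass: class probabilities for a batch of beats
#'
#' @param model An [hctg_model()].
#' @param x Matrix `[B x 188]` of normalized beat windows.
#' @param engine `"fast"` (single-precision C++ engine) or `"reference"`
#'   (pure-R double-precision path); both agree within single-precision
#'   tolerance.
#' @return Matrix `[B x 5]` of class probabilities; each row sums to 1.
#' @export
forward <- function(model, x, engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "hctg_model"))
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (ncol(x) != model$config$input_length) {
    stop("expected input length ", model$config$input_length,
         ", got ", ncol(x))
  }
  if (engine == "reference") {
    return(hctg_forward_ref(model, x)$probabilities)
  }
  out <- cpp_hctg_forward(model$params, model$state, model$pe, x,
                          variant_code(model$config$variant),
                          model$config$n_transformer_layers,
                          model$config$n_heads, FALSE)
  probs <- out$probs
  colnames(probs) <- model$classes
  probs
}

variant_code <- function(variant) {
  match(variant, c("full", "cnn_only", "transformer_only",
                   "concat_no_gate")) - 1L
}

#' @export
predict.hctg_model <- function(object, newdata, type = c("prob", "class"),
                               batch_size = 512L, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "beat_dataset")) newdata$beats else as.matrix(newdata)
  n <- nrow(x)
  probs <- matrix(0, n, object$config$n_classes,
                  dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[idx, ] <- forward(object, x[idx, , drop = FALSE])
  }
  if (type == "prob") return(probs)
  factor(object$classes[apply(probs, 1L, which.max)], levels = object$classes)
}
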