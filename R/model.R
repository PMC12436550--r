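#' Model configuration
#'
#' Fully determines a decoder architecture and all intermediate shapes.
#' Four variants are available:
#'
#' * `model_a` ("2D-Ta"): 2-D CNN over the channels-by-time array
#'   (`C x L -> K x C' x T`), reshape to `T` embeddings of size
#'   `K' = K * C'`, LSTM summary of size `H`, dense head.
#' * `model_a_tt`: as `model_a` but the LSTM is replaced by a temporal
#'   Transformer encoder with a CLS summary token.
#' * `model_a_st`: as `model_a` but with a spatial Transformer encoder over
#'   the `C'` reduced-channel columns at every time step (CLS summary per
#'   step), followed by the LSTM.
#' * `model_b` ("1D-Sa-Ta"): per-channel 1-D CNN with shared filters
#'   (`C x L -> C x K x T`), then for each of the `T` segments a spatial
#'   Transformer encoder over the `C` channel tokens plus a prepended CLS
#'   token (sequence length `C + 1`; encoder parameters shared across
#'   segments), then an LSTM over the `T` CLS outputs, then the dense head.
#'
#' The convolutional front end is fully convolutional: `n_blocks` blocks of
#' valid kernel-3 convolution + ReLU + max-pool 2 along time, so
#' `L -> floor((L - 2) / 2)` per block; with the default 4 blocks,
#' `L = 500 -> T = 29`. For the 2-D variants the channel axis is reduced the
#' same way (kernel-3 conv + pool 2) in every block whose running channel
#' dimension is at least 9, which maps `C = 129 -> C' = 6` and leaves the
#' 8-channel consumer montage unreduced (`C' = 8`).
#'
#' @param variant One of `"model_a"`, `"model_a_tt"`, `"model_a_st"`,
#'   `"model_b"`.
#' @param C,L Input channel count and epoch length (samples).
#' @param K Convolutional feature count (and spatial-token width).
#' @param H LSTM hidden size.
#' @param n_blocks Number of conv blocks in the front end.
#' @param transformer_layers,transformer_heads Encoder depth and head count
#'   (spatial/temporal Transformer variants). The per-head width
#'   `d = d_model / heads` is the attention scaling dimension.
#' @param ff_mult Width multiplier of the encoder's feed-forward sublayer.
#' @param use_channel_embedding Add a learnable per-channel embedding to the
#'   `C` channel tokens of `model_b`, making channel identity visible to
#'   attention (and hence channel-attributable importance). Disable to obtain
#'   a channel-permutation-invariant model.
#' @param head `"gaze"` (2 outputs) or `"fixation"` (1 logit).
#' @param sampling_rate Hz, carried for provenance.
#' @return An object of class `model_config` with derived fields `T_len`,
#'   `C_prime`, `K_prime`, `d_model`, `conv_plan`.
#' @export
model_config <- function(variant = c("model_b", "model_a", "model_a_tt",
                                     "model_a_st"),
                         C, L, K = 128, H = 768, n_blocks = 4,
                         transformer_layers = 2, transformer_heads = 4,
                         ff_mult = 2, use_channel_embedding = TRUE,
                         head = c("gaze", "fixation"), sampling_rate = 500) {
  variant <- match.arg(variant)
  head <- match.arg(head)
  C <- as.integer(C); L <- as.integer(L)
  # temporal plan: kernel-3 valid conv + pool 2 per block
  Lc <- L
  for (i in seq_len(n_blocks)) {
    Lc <- (Lc - 2L) %/% 2L
    if (Lc < 1L) stop("L = ", L, " too short for ", n_blocks, " conv blocks")
  }
  T_len <- Lc
  # channel plan (2-D variants): reduce while the running dim allows it
  conv_plan <- vector("list", n_blocks)
  Cc <- C
  for (i in seq_len(n_blocks)) {
    reduce <- Cc >= 9L
    conv_plan[[i]] <- list(kc = if (reduce) 3L else 1L, pool_c = reduce)
    if (reduce) Cc <- (Cc - 2L) %/% 2L
  }
  C_prime <- if (variant == "model_b") C else Cc
  K_prime <- K * Cc
  d_model <- switch(variant, model_b = K, model_a_st = K,
                    model_a_tt = K_prime, model_a = NA_integer_)
  if (!is.na(d_model) && d_model %% transformer_heads != 0L)
    stop("transformer_heads (", transformer_heads,
         ") must divide the token width (", d_model, ")")
  structure(list(variant = variant, C = C, L = L, K = as.integer(K),
                 H = as.integer(H), n_blocks = as.integer(n_blocks),
                 transformer_layers = as.integer(transformer_layers),
                 transformer_heads = as.integer(transformer_heads),
                 ff_mult = ff_mult,
                 use_channel_embedding = use_channel_embedding,
                 head = head, sampling_rate = sampling_rate,
                 T_len = T_len, C_prime = C_prime, K_prime = K_prime,
                 d_model = d_model, conv_plan = conv_plan,
                 d = if (is.na(d_model)) NA_integer_ else
                   d_model %/% transformer_heads),
            class = "model_config")
}

#' Rebuild a configuration for new input dimensions
#'
#' Used by the sweep protocol: cropping changes `L`, channel reduction
#' changes `C`; all derived shapes are re-inferred under the same kernel plan.
#'
#' @param config A `model_config`.
#' @param C,L New input dimensions (default: unchanged).
#' @return A new `model_config`.
#' @export
reconfigure <- function(config, C = config$C, L = config$L) {
  model_config(config$variant, C = C, L = L, K = config$K, H = config$H,
               n_blocks = config$n_blocks,
               transformer_layers = config$transformer_layers,
               transformer_heads = config$transformer_heads,
               ff_mult = config$ff_mult,
               use_channel_embedding = config$use_channel_embedding,
               head = config$head, sampling_rate = config$sampling_rate)
}

#' The nominal full-scale configuration
#'
#' The configuration whose intermediate shapes reproduce the published
#' dimension table: `C = 129`, `L = 500`, `K = 128`, `H = 768`, giving
#' `T = 29` and (for the 2-D variants) `C' = 6`, `K' = 768`.
#'
#' @param variant,head See [model_config()].
#' @return A `model_config`.
#' @export
nominal_config <- function(variant = "model_b", head = "gaze") {
  geo <- nominal_epoch_geometry()
  model_config(variant, C = geo$C, L = geo$L, K = 128, H = 768,
               head = head, sampling_rate = geo$sampling_rate)
}

#' A desk-scale configuration matched to the synthetic generator
#'
#' Small enough to train on one CPU in minutes: `C = 16`, `L = 128`,
#' `K = 16`, `H = 32`, one encoder layer with two heads.
#'
#' @param variant,head See [model_config()].
#' @param C,L,K,H Override any dimension.
#' @return A `model_config`.
#' @export
desk_config <- function(variant = "model_b", head = "gaze",
                        C = 16, L = 128, K = 16, H = 32) {
  model_config(variant, C = C, L = L, K = K, H = H,
               transformer_layers = 1, transformer_heads = 2,
               head = head, sampling_rate = 128)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %s: C=%d L=%d K=%d -> T=%d C'=%d K'=%d, H=%d, %s head\n",
    x$variant, x$C, x$L, x$K, x$T_len, x$C_prime, x$K_prime, x$H, x$head))
  invisible(x)
}

head_input_size <- function(config) {
  if (config$variant == "model_a_tt") config$K_prime else config$H
}

#' Initialize a decoder model
#'
#' Draws all weights from the standard initializers (He for ReLU-fed layers,
#' Glorot elsewhere, forget-gate bias 1, CLS token and channel embeddings
#' from small-variance normals), deterministically for a given seed.
#'
#' @param config A `model_config`.
#' @param seed Integer seed.
#' @return An object of class `eegaze_model` holding `params`, `config` and
#'   (once trained) the standardization statistics.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed_(seed, {
    p <- list()
    K <- config$K
    p$conv <- vector("list", config$n_blocks)
    for (i in seq_len(config$n_blocks)) {
      fin <- if (i == 1L) 1L else K
      if (config$variant == "model_b") {
        p$conv[[i]] <- list(W = he_mat(K, fin * 3L), b = rep(0, K))
      } else {
        kc <- config$conv_plan[[i]]$kc
        p$conv[[i]] <- list(W = he_mat(K, fin * kc * 3L), b = rep(0, K))
      }
    }
    if (!is.na(config$d_model)) {
      p$cls <- stats::rnorm(config$d_model, sd = 0.02)
      p$encoder <- lapply(seq_len(config$transformer_layers), function(i)
        transformer_layer_init(config$d_model,
                               round(config$ff_mult * config$d_model)))
    }
    if (config$variant == "model_b" && config$use_channel_embedding)
      p$chan_emb <- matrix(stats::rnorm(config$C * K, sd = 0.02),
                           config$C, K)
    if (config$variant != "model_a_tt") {
      D <- switch(config$variant, model_a = config$K_prime, model_a_st = K,
                  model_b = K)
      p$lstm <- lstm_init(D, config$H)
    }
    p$head <- list(W = glorot_mat(if (config$head == "gaze") 2L else 1L,
                                  head_input_size(config)),
                   b = rep(0, if (config$head == "gaze") 2L else 1L))
    p
  })
  structure(list(params = params, config = config, norm_stats = NULL),
            class = "eegaze_model")
}

#' @export
print.eegaze_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<eegaze_model> %s (%s head), %d parameters%s\n",
              x$config$variant, x$config$head, np,
              if (is.null(x$norm_stats)) "" else ", trained"))
  invisible(x)
}

# ---- convolutional front ends ---------------------------------------------

# model_b: X (C, L, B) -> (K, C*B, T); channels share filters and are fully
# independent (merged into the sequence-batch axis, channel fastest).
conv1d_front_fwd <- function(params, config, X) {
  d <- dim(X); C <- d[1L]; B <- d[3L]
  A <- aperm(X, c(1, 3, 2))
  dim(A) <- c(1L, C * B, config$L)
  caches <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    cv <- conv1d_fwd(params$conv[[i]]$W, params$conv[[i]]$b, A, 3L)
    rl <- relu_fwd(cv$out)
    pl <- pool1d_fwd(rl$out)
    caches[[i]] <- list(cv = cv, rl = rl, pl = pl)
    A <- pl$out
  }
  list(out = A, caches = caches)
}

conv1d_front_bwd <- function(params, config, caches, dA) {
  g <- vector("list", config$n_blocks)
  for (i in rev(seq_len(config$n_blocks))) {
    dA <- pool1d_bwd(caches[[i]]$pl, dA)
    dA <- relu_bwd(caches[[i]]$rl, dA)
    cb <- conv1d_bwd(params$conv[[i]]$W, caches[[i]]$cv, dA,
                     want_dA = i > 1L)
    g[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dA
  }
  list(conv = g)
}

# model_a family: X (C, L, B) -> (K, C', T, B).
conv2d_front_fwd <- function(params, config, X) {
  d <- dim(X); B <- d[3L]
  A <- X
  dim(A) <- c(1L, d[1L], d[2L], B)
  caches <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    plan <- config$conv_plan[[i]]
    cv <- conv2d_fwd(params$conv[[i]]$W, params$conv[[i]]$b, A,
                     plan$kc, 3L)
    rl <- relu_fwd(cv$out)
    pt <- pool2d_fwd(rl$out, axis = 3L)
    pc <- if (plan$pool_c) pool2d_fwd(pt$out, axis = 2L) else NULL
    caches[[i]] <- list(cv = cv, rl = rl, pt = pt, pc = pc)
    A <- if (is.null(pc)) pt$out else pc$out
  }
  list(out = A, caches = caches)
}

conv2d_front_bwd <- function(params, config, caches, dA) {
  g <- vector("list", config$n_blocks)
  for (i in rev(seq_len(config$n_blocks))) {
    if (!is.null(caches[[i]]$pc)) dA <- pool2d_bwd(caches[[i]]$pc, dA)
    dA <- pool2d_bwd(caches[[i]]$pt, dA)
    dA <- relu_bwd(caches[[i]]$rl, dA)
    cb <- conv2d_bwd(params$conv[[i]]$W, caches[[i]]$cv, dA,
                     want_dA = i > 1L)
    g[[i]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dA
  }
  list(conv = g)
}

# ---- shared encoder application -------------------------------------------

# Apply the Transformer encoder stack to tokens (d_model, S, B); returns the
# full token output, per-layer caches, and the last layer's head-averaged
# attention (S, S, B).
encoder_fwd <- function(params, config, X) {
  caches <- vector("list", config$transformer_layers)
  att <- NULL
  for (l in seq_len(config$transformer_layers)) {
    lf <- transformer_layer_fwd(params$encoder[[l]], X,
                                config$transformer_heads)
    caches[[l]] <- lf$cache
    att <- lf$att_mean
    X <- lf$out
  }
  list(out = X, caches = caches, att = att)
}

encoder_bwd <- function(params, config, caches, dX) {
  grads <- vector("list", config$transformer_layers)
  for (l in rev(seq_len(config$transformer_layers))) {
    lb <- transformer_layer_bwd(params$encoder[[l]], caches[[l]], dX)
    grads[[l]] <- lb$grads
    dX <- lb$dX
  }
  list(dX = dX, encoder = grads)
}

# ---- full forward pass ----------------------------------------------------

#' Forward pass of a decoder
#'
#' Maps a batch of epochs to task outputs. For the spatial-Transformer
#' variants (`model_b`, `model_a_st`) the last encoder layer's head-averaged
#' attention matrices are returned for every temporal segment; requesting
#' attention from a variant without a spatial Transformer is an error.
#'
#' @param model An `eegaze_model`.
#' @param X Numeric array `C x L x B` (already standardized if the model was
#'   trained on standardized data; see [predict_bundle()]).
#' @param want_cache Keep all intermediate activations (training).
#' @param want_attention Return the attention record.
#' @return List with `output` (`n_outputs x B`), optionally `attention`
#'   (`S x S x T x B`, `S` = token count) and `cache`.
#' @export
model_forward <- function(model, X, want_cache = FALSE,
                          want_attention = FALSE) {
  config <- model$config; params <- model$params
  d <- dim(X)
  if (length(d) == 2L) { dim(X) <- c(d, 1L); d <- dim(X) }
  if (d[1L] != config$C || d[2L] != config$L)
    stop("input shape ", d[1L], "x", d[2L], " does not match config ",
         config$C, "x", config$L)
  if (want_attention && !(config$variant %in% c("model_b", "model_a_st")))
    stop("variant ", config$variant, " has no spatial Transformer; ",
         "no attention record is available")
  B <- d[3L]
  switch(config$variant,
    model_b = forward_model_b(params, config, X, B, want_cache,
                              want_attention),
    model_a = forward_model_a(params, config, X, B, want_cache),
    model_a_tt = forward_model_a_tt(params, config, X, B, want_cache),
    model_a_st = forward_model_a_st(params, config, X, B, want_cache,
                                    want_attention))
}

forward_model_b <- function(params, config, X, B, want_cache,
                            want_attention) {
  C <- config$C; K <- config$K; Tn <- config$T_len
  fr <- conv1d_front_fwd(params, config, X)   # (K, T, C*B)
  S <- C + 1L
  emb <- if (config$use_channel_embedding) t(params$chan_emb) else NULL
  seq_in <- vector("list", Tn)
  enc_caches <- vector("list", Tn)
  att <- if (want_attention) array(0, dim = c(S, S, Tn, B)) else NULL
  for (t in seq_len(Tn)) {
    tok <- fr$out[, , t]
    dim(tok) <- c(K, C, B)
    if (!is.null(emb)) tok <- tok + as.vector(emb)  # recycled over B
    Xt <- array(0, dim = c(K, S, B))
    Xt[, 1L, ] <- params$cls
    Xt[, 2:S, ] <- tok
    ef <- encoder_fwd(params, config, Xt)
    if (want_attention) att[, , t, ] <- ef$att
    seq_in[[t]] <- matrix(ef$out[, 1L, ], K, B)
    if (want_cache) enc_caches[[t]] <- ef$caches
  }
  ls <- lstm_fwd(params$lstm, seq_in)
  out <- linear_fwd(params$head$W, params$head$b, ls$h)
  cache <- if (want_cache) list(front = fr, enc = enc_caches, lstm = ls,
                                head_in = ls$h, B = B) else NULL
  list(output = out, attention = att, cache = cache)
}

forward_model_a <- function(params, config, X, B, want_cache) {
  fr <- conv2d_front_fwd(params, config, X)   # (K, C', T, B)
  Kp <- config$K_prime; Tn <- config$T_len
  seq_in <- lapply(seq_len(Tn), function(t) {
    v <- fr$out[, , t, ]
    dim(v) <- c(Kp, B)
    v
  })
  ls <- lstm_fwd(params$lstm, seq_in)
  out <- linear_fwd(params$head$W, params$head$b, ls$h)
  cache <- if (want_cache) list(front = fr, lstm = ls, head_in = ls$h,
                                B = B) else NULL
  list(output = out, attention = NULL, cache = cache)
}

forward_model_a_tt <- function(params, config, X, B, want_cache) {
  fr <- conv2d_front_fwd(params, config, X)
  Kp <- config$K_prime; Tn <- config$T_len
  S <- Tn + 1L
  Xt <- array(0, dim = c(Kp, S, B))
  Xt[, 1L, ] <- params$cls
  for (t in seq_len(Tn)) {
    v <- fr$out[, , t, ]
    dim(v) <- c(Kp, B)
    Xt[, t + 1L, ] <- v
  }
  ef <- encoder_fwd(params, config, Xt)
  summary_vec <- matrix(ef$out[, 1L, ], Kp, B)
  out <- linear_fwd(params$head$W, params$head$b, summary_vec)
  cache <- if (want_cache) list(front = fr, enc = ef$caches,
                                head_in = summary_vec, B = B) else NULL
  list(output = out, attention = NULL, cache = cache)
}

forward_model_a_st <- function(params, config, X, B, want_cache,
                               want_attention) {
  fr <- conv2d_front_fwd(params, config, X)   # (K, C', T, B)
  K <- config$K; Cp <- config$C_prime; Tn <- config$T_len
  S <- Cp + 1L
  seq_in <- vector("list", Tn)
  enc_caches <- vector("list", Tn)
  att <- if (want_attention) array(0, dim = c(S, S, Tn, B)) else NULL
  for (t in seq_len(Tn)) {
    tok <- fr$out[, , t, ]
    dim(tok) <- c(K, Cp, B)
    Xt <- array(0, dim = c(K, S, B))
    Xt[, 1L, ] <- params$cls
    Xt[, 2:S, ] <- tok
    ef <- encoder_fwd(params, config, Xt)
    if (want_attention) att[, , t, ] <- ef$att
    seq_in[[t]] <- matrix(ef$out[, 1L, ], K, B)
    if (want_cache) enc_caches[[t]] <- ef$caches
  }
  ls <- lstm_fwd(params$lstm, seq_in)
  out <- linear_fwd(params$head$W, params$head$b, ls$h)
  cache <- if (want_cache) list(front = fr, enc = enc_caches, lstm = ls,
                                head_in = ls$h, B = B) else NULL
  list(output = out, attention = att, cache = cache)
}

# ---- full backward pass ---------------------------------------------------

# dOut: gradient of the loss wrt the head output (n_outputs, B). Returns
# parameter gradients in the same nested structure as model$params.
model_backward <- function(model, fw, dOut) {
  config <- model$config; params <- model$params
  hb <- linear_bwd(params$head$W, fw$cache$head_in, dOut)
  grads <- list(head = list(W = hb$dW, b = hb$db))
  switch(config$variant,
    model_b = backward_model_b(params, config, fw, hb$dX, grads),
    model_a = backward_model_a(params, config, fw, hb$dX, grads),
    model_a_tt = backward_model_a_tt(params, config, fw, hb$dX, grads),
    model_a_st = backward_model_a_st(params, config, fw, hb$dX, grads))
}

add_encoder_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (l in seq_along(acc))
    for (nm in names(acc[[l]]))
      acc[[l]][[nm]] <- acc[[l]][[nm]] + g[[l]][[nm]]
  acc
}

backward_model_b <- function(params, config, fw, dh, grads) {
  C <- config$C; K <- config$K; Tn <- config$T_len; S <- C + 1L
  B <- fw$cache$B
  lb <- lstm_bwd(params$lstm, fw$cache$lstm$cache, dh)
  grads$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
  dConv <- array(0, dim = c(K, C * B, Tn))
  enc_acc <- NULL
  dcls <- rep(0, K)
  demb <- if (config$use_channel_embedding) params$chan_emb * 0 else NULL
  for (t in seq_len(Tn)) {
    dXt <- array(0, dim = c(K, S, B))
    dXt[, 1L, ] <- lb$dxs[[t]]
    eb <- encoder_bwd(params, config, fw$cache$enc[[t]], dXt)
    enc_acc <- add_encoder_grads(enc_acc, eb$encoder)
    dcls <- dcls + rowSums(matrix(eb$dX[, 1L, ], K, B))
    dtok <- eb$dX[, 2:S, , drop = FALSE]
    if (!is.null(demb)) {
      # sum over the batch axis: (K, C, B) -> (K, C)
      sums <- matrix(rowSums(matrix(dtok, K * C, B)), K, C)
      demb <- demb + t(sums)
    }
    dConv[, , t] <- matrix(dtok, K, C * B)
  }
  grads$encoder <- enc_acc
  grads$cls <- dcls
  if (!is.null(demb)) grads$chan_emb <- demb
  fb <- conv1d_front_bwd(params, config, fw$cache$front$caches, dConv)
  grads$conv <- fb$conv
  grads
}

backward_model_a <- function(params, config, fw, dh, grads) {
  K <- config$K; Cp <- config$C_prime; Tn <- config$T_len
  B <- fw$cache$B
  lb <- lstm_bwd(params$lstm, fw$cache$lstm$cache, dh)
  grads$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
  dVol <- array(0, dim = c(K, Cp, Tn, B))
  for (t in seq_len(Tn)) {
    dv <- lb$dxs[[t]]
    dim(dv) <- c(K, Cp, B)
    dVol[, , t, ] <- dv
  }
  fb <- conv2d_front_bwd(params, config, fw$cache$front$caches, dVol)
  grads$conv <- fb$conv
  grads
}

backward_model_a_tt <- function(params, config, fw, dsum, grads) {
  Kp <- config$K_prime; Tn <- config$T_len; S <- Tn + 1L
  B <- fw$cache$B
  dXt <- array(0, dim = c(Kp, S, B))
  dXt[, 1L, ] <- dsum
  eb <- encoder_bwd(params, config, fw$cache$enc, dXt)
  grads$encoder <- eb$encoder
  grads$cls <- rowSums(matrix(eb$dX[, 1L, ], Kp, B))
  Cp <- config$C_prime; K <- config$K
  dVol <- array(0, dim = c(K, Cp, Tn, B))
  for (t in seq_len(Tn)) {
    dv <- eb$dX[, t + 1L, ]
    dim(dv) <- c(K, Cp, B)
    dVol[, , t, ] <- dv
  }
  fb <- conv2d_front_bwd(params, config, fw$cache$front$caches, dVol)
  grads$conv <- fb$conv
  grads
}

backward_model_a_st <- function(params, config, fw, dh, grads) {
  K <- config$K; Cp <- config$C_prime; Tn <- config$T_len; S <- Cp + 1L
  B <- fw$cache$B
  lb <- lstm_bwd(params$lstm, fw$cache$lstm$cache, dh)
  grads$lstm <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
  dVol <- array(0, dim = c(K, Cp, Tn, B))
  enc_acc <- NULL
  dcls <- rep(0, K)
  for (t in seq_len(Tn)) {
    dXt <- array(0, dim = c(K, S, B))
    dXt[, 1L, ] <- lb$dxs[[t]]
    eb <- encoder_bwd(params, config, fw$cache$enc[[t]], dXt)
    enc_acc <- add_encoder_grads(enc_acc, eb$encoder)
    dcls <- dcls + rowSums(matrix(eb$dX[, 1L, ], K, B))
    dVol[, , t, ] <- eb$dX[, 2:S, , drop = FALSE]
  }
  grads$encoder <- enc_acc
  grads$cls <- dcls
  fb <- conv2d_front_bwd(params, config, fw$cache$front$caches, dVol)
  grads$conv <- fb$conv
  grads
}
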