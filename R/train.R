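#' Training configuration
#'
#' Optimizer and schedule defaults are package choices, declared here and
#' logged with every run: Adam at learning rate 1e-3, minibatches of 32, early
#' stopping on validation loss with best-weight restoration. The loss is mean
#' squared error (over the `2n` scalar residuals) for gaze regression and
#' binary cross-entropy on the logit for fixation classification.
#'
#' @param task `"gaze"` or `"fixation"`; must match the model head and the
#'   bundle's labels.
#' @param epochs Maximum training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and batch order.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param standardize Apply per-channel z-scoring with training-split
#'   statistics before modeling (the statistics travel with the model).
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("gaze", "fixation"), epochs = 30,
                         batch_size = 32, learning_rate = 1e-3, seed = 1L,
                         early_stopping_patience = 10, standardize = TRUE,
                         verbose = FALSE) {
  task <- match.arg(task)
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(task = task, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 standardize = standardize, verbose = verbose),
            class = "train_config")
}

# ---- losses ---------------------------------------------------------------

# output (2, B), target (2, B): the 1/(2B) convention, matching the RMSE
# metric definition.
loss_gaze <- function(output, target) {
  r <- output - target
  B <- ncol(output)
  list(loss = sum(r^2) / (2 * B), dout = r / B)
}

# output (1, B) logits, target length-B flags. Numerically stable BCE.
loss_fixation <- function(output, target) {
  z <- as.numeric(output)
  B <- length(z)
  l <- mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  dout <- matrix((sigmoid(z) - target) / B, 1L, B)
  list(loss = l, dout = dout)
}

# ---- Adam over nested parameter lists -------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- training -------------------------------------------------------------

batch_targets <- function(bundle, idx, task) {
  if (task == "gaze") t(bundle$labels[idx, , drop = FALSE])
  else bundle$labels[idx]
}

batch_loss <- function(task, output, target) {
  if (task == "gaze") loss_gaze(output, target)
  else loss_fixation(output, target)
}

#' Train a decoder on a bundle
#'
#' Runs seeded minibatch Adam on the training split, monitors the loss on the
#' validation split after every epoch, and returns the model restored to its
#' best-validation weights. Fully deterministic given `(data, configs, seed)`.
#'
#' @param bundle An `eeg_bundle` with a split assignment (epochs with no
#'   split are ignored; if no validation epochs exist the training split is
#'   monitored instead).
#' @param model_config A [model_config()] matching the bundle's `C`, `L`.
#' @param tc A [train_config()] whose task matches the model head.
#' @return List of class `eegaze_fit` with elements `model` (trained
#'   `eegaze_model`, standardization statistics attached), `history` (tibble
#'   of per-epoch train/val loss) and `best_epoch`.
#' @export
train_model <- function(bundle, model_config, tc = train_config()) {
  stopifnot(inherits(bundle, "eeg_bundle"), inherits(model_config,
                                                     "model_config"),
            inherits(tc, "train_config"))
  d <- dim(bundle$signals)
  if (d[1L] != model_config$C || d[2L] != model_config$L)
    stop("bundle shape ", d[1L], "x", d[2L], " does not match model config ",
         model_config$C, "x", model_config$L)
  if ((tc$task == "gaze") != (model_config$head == "gaze"))
    stop("train task and model head disagree")
  if (bundle$label_type != tc$task)
    stop("bundle labels are ", bundle$label_type, " but task is ", tc$task)
  idx_tr <- split_indices(bundle, "train")
  if (length(idx_tr) == 0L) stop("bundle has no training epochs")
  idx_val <- split_indices(bundle, "val")
  if (length(idx_val) == 0L) idx_val <- idx_tr
  stats <- NULL
  if (tc$standardize) {
    stats <- channel_stats(bundle)
    bundle <- standardize_bundle(bundle, stats)
  }
  # gaze targets are screen coordinates (order 1e2-1e3 mm); train against
  # z-scored labels (training-split statistics) and unscale at prediction
  label_stats <- NULL
  if (tc$task == "gaze") {
    y_tr <- bundle$labels[idx_tr, , drop = FALSE]
    label_stats <- list(mu = colMeans(y_tr),
                        sd = pmax(apply(y_tr, 2, stats::sd), 1e-12))
    bundle$labels <- sweep(sweep(bundle$labels, 2, label_stats$mu), 2,
                           label_stats$sd, "/")
  }
  with_seed_(tc$seed, {
    model <- init_model(model_config, seed = tc$seed)
    model$norm_stats <- stats
    model$label_stats <- label_stats
    state <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, epoch = 0L)
    patience_left <- tc$early_stopping_patience
    hist <- vector("list", tc$epochs)
    for (ep in seq_len(tc$epochs)) {
      perm <- idx_tr[sample.int(length(idx_tr))]
      nb <- ceiling(length(perm) / tc$batch_size)
      tr_loss <- 0
      for (bi in seq_len(nb)) {
        bidx <- perm[((bi - 1L) * tc$batch_size + 1L):
                       min(bi * tc$batch_size, length(perm))]
        X <- bundle$signals[, , bidx, drop = FALSE]
        target <- batch_targets(bundle, bidx, tc$task)
        fw <- model_forward(model, X, want_cache = TRUE)
        ls <- batch_loss(tc$task, fw$output, target)
        tr_loss <- tr_loss + ls$loss * length(bidx)
        grads <- model_backward(model, fw, ls$dout)
        upd <- adam_step(model$params, grads, state, tc$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      tr_loss <- tr_loss / length(perm)
      val_loss <- eval_loss(model, bundle, idx_val, tc)
      hist[[ep]] <- c(epoch = ep, train_loss = tr_loss, val_loss = val_loss)
      if (tc$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_loss,
                        val_loss))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = model$params, epoch = ep)
        patience_left <- tc$early_stopping_patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
    model$params <- best$params
    structure(list(model = model,
                   history = tibble::as_tibble(do.call(rbind,
                     hist[!vapply(hist, is.null, TRUE)])),
                   best_epoch = best$epoch, val_loss = best$loss,
                   train_config = tc),
              class = "eegaze_fit")
  })
}

eval_loss <- function(model, bundle, idx, tc, batch_size = 128L) {
  total <- 0
  for (start in seq(1L, length(idx), by = batch_size)) {
    bidx <- idx[start:min(start + batch_size - 1L, length(idx))]
    X <- bundle$signals[, , bidx, drop = FALSE]
    fw <- model_forward(model, X)
    ls <- batch_loss(tc$task, fw$output,
                     batch_targets(bundle, bidx, tc$task))
    total <- total + ls$loss * length(bidx)
  }
  total / length(idx)
}

#' Predict on a bundle
#'
#' Applies the model's stored standardization statistics (if it was trained
#' with standardization), then runs the forward pass in batches.
#'
#' @param model An `eegaze_model`.
#' @param bundle An `eeg_bundle` with matching geometry.
#' @param indices Epoch indices to predict (default: all).
#' @param attention Also return the spatial-attention record, an
#'   `S x S x T x n` array (spatial-Transformer variants only).
#' @param batch_size Forward batch size.
#' @return List with `output` (`n x n_outputs` matrix; for a fixation head
#'   also `prob`, the logistic-transformed probabilities) and optionally
#'   `attention`.
#' @export
predict_bundle <- function(model, bundle, indices = NULL, attention = FALSE,
                           batch_size = 64L) {
  if (is.null(indices)) indices <- seq_len(n_epochs(bundle))
  if (!is.null(model$norm_stats))
    bundle <- standardize_bundle(bundle, model$norm_stats)
  outs <- NULL; atts <- NULL
  for (start in seq(1L, length(indices), by = batch_size)) {
    bidx <- indices[start:min(start + batch_size - 1L, length(indices))]
    X <- bundle$signals[, , bidx, drop = FALSE]
    fw <- model_forward(model, X, want_attention = attention)
    outs <- cbind(outs, fw$output)
    if (attention) atts <- c(atts, list(fw$attention))
  }
  res <- list(output = t(outs))
  if (!is.null(model$label_stats))
    res$output <- sweep(sweep(res$output, 2, model$label_stats$sd, "*"),
                        2, model$label_stats$mu, "+")
  if (model$config$head == "fixation")
    res$prob <- as.numeric(sigmoid(res$output))
  if (attention) {
    d <- dim(atts[[1L]])
    res$attention <- array(unlist(atts, use.names = FALSE),
                           dim = c(d[1L], d[2L], d[3L],
                                   length(indices)))
  }
  res
}

#' Evaluate a trained model on one split
#'
#' @param model An `eegaze_model`.
#' @param bundle An `eeg_bundle` with split assignment.
#' @param split Which split to score.
#' @return For a gaze head, the [evaluate_regression()] list; for a fixation
#'   head, the [evaluate_classification()] list.
#' @export
evaluate_model <- function(model, bundle, split = "test") {
  idx <- split_indices(bundle, split)
  if (length(idx) == 0L) stop("no epochs in split '", split, "'")
  pred <- predict_bundle(model, bundle, idx)
  if (model$config$head == "gaze")
    evaluate_regression(bundle$labels[idx, , drop = FALSE], pred$output)
  else
    evaluate_classification(bundle$labels[idx], pred$prob)
}

#' Constant-predictor baseline for gaze regression
#'
#' RMSE (1/(2n) convention) of always predicting the training-split mean
#' gaze point — the floor any informative decoder must beat.
#'
#' @param bundle A gaze `eeg_bundle` with split assignment.
#' @param split Evaluation split.
#' @return The baseline list from [evaluate_regression()].
#' @export
constant_baseline <- function(bundle, split = "test") {
  tr <- split_indices(bundle, "train")
  te <- split_indices(bundle, split)
  mu <- colMeans(bundle$labels[tr, , drop = FALSE])
  pred <- matrix(mu, length(te), 2, byrow = TRUE)
  evaluate_regression(bundle$labels[te, , drop = FALSE], pred)
}
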