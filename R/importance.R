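#' Extract the CLS attention rows
#'
#' From the last-layer self-attention matrices of the `T` spatial Transformer
#' encoders (each `(C+1) x (C+1)`, row-stochastic, CLS token first), keeps
#' the first row — the attention the CLS summary pays to the channel tokens —
#' and drops the CLS column (the CLS self-attention mass). Each returned row
#' therefore sums to one minus the CLS self-attention entry.
#'
#' @param attention_record Either a list of `T` square matrices or an
#'   `S x S x T` array (an `S x S x T x 1` array is accepted).
#' @return A `T x C` matrix of CLS attention rows.
#' @export
extract_cls_attention <- function(attention_record) {
  if (is.array(attention_record) && !is.list(attention_record)) {
    d <- dim(attention_record)
    if (length(d) == 4L) {
      if (d[4L] != 1L) stop("pass one instance at a time")
      dim(attention_record) <- d[1:3]
      d <- d[1:3]
    }
    if (length(d) != 3L || d[1L] != d[2L])
      stop("attention matrices must be square")
    attention_record <- lapply(seq_len(d[3L]),
                               function(t) attention_record[, , t])
  }
  S <- nrow(attention_record[[1L]])
  rows <- vapply(attention_record, function(A) {
    if (!is.matrix(A) || nrow(A) != ncol(A) || nrow(A) != S)
      stop("attention matrices must be square and equally sized")
    A[1L, -1L]
  }, numeric(S - 1L))
  t(rows)
}

#' Per-instance channel importance
#'
#' The arithmetic mean of the CLS attention rows over the `T` temporal
#' segments: `alpha^(i) = (1/T) sum_t a_t^(i)`.
#'
#' @param cls_rows `T x C` matrix from [extract_cls_attention()].
#' @return Numeric vector of length `C`.
#' @export
instance_importance <- function(cls_rows) {
  cls_rows <- as.matrix(cls_rows)
  if (nrow(cls_rows) < 1L) stop("need at least one segment row")
  colMeans(cls_rows)
}

#' Aggregate channel importance over instances
#'
#' The grand channel-importance vector `alpha = (1/m) sum_i alpha^(i)`.
#' Entries lie in `[0, 1]` and sum to at most 1: the CLS self-attention mass
#' is excluded and no renormalization is applied, so the values are raw
#' softmax attention masses.
#'
#' @param per_instance `m x C` matrix (or list of length-`C` vectors) of
#'   per-instance importances.
#' @param montage Optional `eeg_montage` naming the `C` channels.
#' @param n_segments Number of temporal segments `T` (metadata).
#' @param cls_self_mass Mean CLS self-attention entry (metadata; filled in
#'   by [compute_importance()]).
#' @return An object of class `importance_vector` with fields `alpha`,
#'   `n_instances`, `n_segments`, `montage`, `cls_self_mass`.
#' @export
aggregate_importance <- function(per_instance, montage = NULL,
                                 n_segments = NA_integer_,
                                 cls_self_mass = NA_real_) {
  if (is.list(per_instance)) {
    lens <- lengths(per_instance)
    if (length(unique(lens)) != 1L)
      stop("per-instance vectors have inconsistent lengths")
    per_instance <- do.call(rbind, per_instance)
  }
  per_instance <- as.matrix(per_instance)
  if (nrow(per_instance) < 1L) stop("need at least one instance")
  alpha <- colMeans(per_instance)
  if (!is.null(montage)) {
    if (length(montage$names) != length(alpha))
      stop("montage size != channel count")
    names(alpha) <- montage$names
  }
  structure(list(alpha = alpha, n_instances = nrow(per_instance),
                 n_segments = n_segments, montage = montage,
                 cls_self_mass = cls_self_mass),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat(sprintf("<importance_vector> %d channels, m = %d instances, T = %s\n",
              length(x$alpha), x$n_instances, x$n_segments))
  top <- utils::head(order(-x$alpha), 5)
  lab <- if (is.null(names(x$alpha))) top else names(x$alpha)[top]
  cat("  top:", paste(sprintf("%s (%.3f)", lab, x$alpha[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Attention-derived channel importance of a trained model
#'
#' Runs the model over the requested split, collects the last-layer spatial
#' attention of every instance, and aggregates the CLS rows into the
#' per-channel importance vector (mean over segments, then over instances).
#' Multi-head attention is averaged over heads before the CLS row is taken.
#' Only the spatial-Transformer variants (`model_b`, `model_a_st`) carry an
#' attention record.
#'
#' @param model A trained `eegaze_model`.
#' @param bundle An `eeg_bundle`.
#' @param split Which split to use (default `"test"`, the reporting choice).
#' @param max_instances Cap on the number of instances (memory guard).
#' @return An `importance_vector`. For `model_b` the channels are the
#'   bundle's physical electrodes and a montage with their names is attached.
#' @export
compute_importance <- function(model, bundle, split = "test",
                               max_instances = 500L) {
  idx <- split_indices(bundle, split)
  if (length(idx) == 0L) idx <- seq_len(n_epochs(bundle))
  if (length(idx) > max_instances) idx <- idx[seq_len(max_instances)]
  pred <- predict_bundle(model, bundle, idx, attention = TRUE)
  att <- pred$attention        # S x S x T x m
  d <- dim(att)
  m <- d[4L]; Tn <- d[3L]
  per_inst <- matrix(0, m, d[1L] - 1L)
  self_mass <- numeric(m)
  for (i in seq_len(m)) {
    rows <- extract_cls_attention(att[, , , i, drop = FALSE])
    per_inst[i, ] <- instance_importance(rows)
    self_mass[i] <- mean(att[1L, 1L, , i])
  }
  mont <- if (model$config$variant == "model_b")
    montage_1020(bundle$channel_names) else NULL
  aggregate_importance(per_inst, montage = mont, n_segments = Tn,
                       cls_self_mass = mean(self_mass))
}

#' Top-fraction channel selection
#'
#' The `ceiling(fraction * C)` channels with the highest importance, in
#' decreasing order of importance; ties broken by channel index (ascending).
#' With `fraction = 0.25` over 128 scalp channels this selects 32 channels,
#' the published top-25% visualization.
#'
#' @param importance An `importance_vector`.
#' @param fraction Fraction of channels to keep, in `(0, 1]`.
#' @return Integer vector of channel indices (named with channel labels when
#'   available), importance-descending.
#' @export
top_fraction_channels <- function(importance, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  alpha <- importance$alpha
  k <- ceiling(fraction * length(alpha))
  ord <- order(-alpha, seq_along(alpha))[seq_len(k)]
  out <- ord
  if (!is.null(names(alpha))) names(out) <- names(alpha)[ord]
  out
}

#' Export an importance ranking and topographic map
#'
#' Always writes the ranked table as CSV (`channel`, `alpha`, `rank`). If the
#' montage carries scalp positions, additionally renders a unit-disc
#' topographic map (head outline, electrodes colored by importance) to PNG;
#' without positions a warning is raised and only the CSV is written.
#'
#' @param importance An `importance_vector`.
#' @param path Output PNG path; the CSV replaces the extension with `.csv`.
#' @return Invisibly, a list with `csv` and `png` (the latter `NA` when no
#'   map was drawn).
#' @export
export_topomap <- function(importance, path) {
  alpha <- importance$alpha
  ord <- order(-alpha, seq_along(alpha))
  chan <- if (is.null(names(alpha))) as.character(ord) else names(alpha)[ord]
  csv_path <- sub("\\.[A-Za-z]+$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(
    data.frame(channel = chan, alpha = alpha[ord],
               rank = seq_along(ord)),
    csv_path, row.names = FALSE, quote = FALSE)
  mont <- importance$montage
  if (is.null(mont) || is.null(mont$positions)) {
    warning("montage positions unavailable; wrote CSV only")
    return(invisible(list(csv = csv_path, png = NA_character_)))
  }
  df <- data.frame(x = mont$positions$x, y = mont$positions$y,
                   alpha = as.numeric(alpha), label = mont$names)
  df <- df[stats::complete.cases(df[, c("x", "y")]), ]
  theta <- seq(0, 2 * pi, length.out = 200)
  head_df <- data.frame(hx = 1.05 * cos(theta), hy = 1.05 * sin(theta))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = head_df, ggplot2::aes(x = hx, y = hy),
                       inherit.aes = FALSE, linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = alpha), size = 9) +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 2.4,
                       vjust = -1.6) +
    ggplot2::scale_color_viridis_c(name = expression(alpha)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Attention-derived channel importance")
  ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 120)
  invisible(list(csv = csv_path, png = path))
}
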