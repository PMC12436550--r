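#' Central signal cropping
#'
#' Keeps the central fraction `gamma = 1 - 2 * rho` of the epoch, removing a
#' ratio `rho` of samples from each end: columns `[m + 1, L - m]` are retained
#' with `m = floor(rho * L)`, so the new length is `L' = L - 2 * m`. On the
#' nominal grid (`L = 500`, `rho` in `{0, 0.1, 0.2, 0.3}`) this is exact:
#' `rho = 0.3` keeps exactly `gamma * L = 200` samples. Labels, channel order
#' and metadata are unchanged.
#'
#' @param x An `eeg_epoch` or `eeg_bundle`.
#' @param rho Cropping ratio in `[0, 0.5)`.
#' @return Object of the same class with cropped signals.
#' @export
crop_signal <- function(x, rho) UseMethod("crop_signal")

crop_cols <- function(L, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 0.5)
    stop("rho must lie in [0, 0.5); got ", rho)
  m <- floor(rho * L)
  if (L - 2 * m < 1L) stop("cropping at rho = ", rho, " leaves no samples")
  seq.int(m + 1L, L - m)
}

#' @export
crop_signal.eeg_epoch <- function(x, rho) {
  keep <- crop_cols(ncol(x$signal), rho)
  x$signal <- x$signal[, keep, drop = FALSE]
  validate_eeg_epoch(x)
  x
}

#' @export
crop_signal.eeg_bundle <- function(x, rho) {
  keep <- crop_cols(dim(x$signals)[2L], rho)
  x$signals <- x$signals[, keep, , drop = FALSE]
  validate_eeg_bundle(x)
  x
}

#' Restrict to a channel montage
#'
#' Returns the epoch or bundle restricted to the montage's channels, in
#' montage order. Name matching is case-insensitive (the literature mixes
#' "OZ" and "Oz"); an unresolvable montage label is an error naming it.
#'
#' @param x An `eeg_epoch` or `eeg_bundle`.
#' @param montage An `eeg_montage`.
#' @return Object of the same class with channels in montage order.
#' @export
select_channels <- function(x, montage) UseMethod("select_channels")

match_montage <- function(channel_names, montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  idx <- match(tolower(montage$names), tolower(channel_names))
  if (anyNA(idx))
    stop("montage channel(s) not found in epoch: ",
         paste(montage$names[is.na(idx)], collapse = ", "))
  idx
}

#' @export
select_channels.eeg_epoch <- function(x, montage) {
  idx <- match_montage(x$channel_names, montage)
  x$signal <- x$signal[idx, , drop = FALSE]
  x$channel_names <- x$channel_names[idx]
  validate_eeg_epoch(x)
  x
}

#' @export
select_channels.eeg_bundle <- function(x, montage) {
  idx <- match_montage(x$channel_names, montage)
  x$signals <- x$signals[idx, , , drop = FALSE]
  x$channel_names <- x$channel_names[idx]
  validate_eeg_bundle(x)
  x
}

#' Assemble the fixation-classification dataset
#'
#' The fixation task is built by combining two gaze-task bundles: epochs of
#' the angle/amplitude task are the positive (fixation) examples and epochs of
#' the absolute-position task the negative ones. The split assignment of the
#' result is the union of the inputs' assignments, so benchmark-provided
#' partitions are preserved. At the benchmark's full scale (17,830 positives,
#' 21,464 negatives) the classes are mostly balanced: ~45% / 55%.
#'
#' @param positives An `eeg_bundle` whose epochs become label 1.
#' @param negatives An `eeg_bundle` whose epochs become label 0.
#' @return An `eeg_bundle` with `label_type = "fixation"`.
#' @export
build_fixation_dataset <- function(positives, negatives) {
  stopifnot(inherits(positives, "eeg_bundle"), inherits(negatives, "eeg_bundle"))
  dp <- dim(positives$signals); dn <- dim(negatives$signals)
  if (dp[1L] != dn[1L] || dp[2L] != dn[2L])
    stop("incompatible shapes: positives ", dp[1L], "x", dp[2L],
         " vs negatives ", dn[1L], "x", dn[2L])
  if (!identical(tolower(positives$channel_names),
                 tolower(negatives$channel_names)))
    stop("bundles must share channel names")
  n_pos <- dp[3L]; n_neg <- dn[3L]
  signals <- array(0, dim = c(dp[1L], dp[2L], n_pos + n_neg))
  if (n_pos > 0) signals[, , seq_len(n_pos)] <- positives$signals
  if (n_neg > 0) signals[, , n_pos + seq_len(n_neg)] <- negatives$signals
  eeg_bundle(signals, positives$channel_names, positives$sampling_rate,
             labels = c(rep(1, n_pos), rep(0, n_neg)),
             label_type = "fixation", source_task = positives$source_task,
             subject_id = c(positives$subject_id, negatives$subject_id),
             split = c(positives$split, negatives$split))
}

#' Deterministic train/val/test split
#'
#' Randomly assigns every epoch to exactly one split. Split sizes are
#' floor-based with the remainder assigned to the training split, so for
#' `n = 1000` and fractions `(0.7, 0.15, 0.15)` the sizes are 700/150/150 and
#' for `n = 7` they are 5/1/1. The assignment is a pure function of
#' `(n, fractions, seed)`.
#'
#' @param bundle An `eeg_bundle`.
#' @param fractions Positive train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @return The bundle with its `split` field assigned.
#' @export
split_dataset <- function(bundle, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three positive numbers summing to 1")
  n <- n_epochs(bundle)
  n_val <- floor(fractions[2L] * n)
  n_test <- floor(fractions[3L] * n)
  n_train <- n - n_val - n_test
  perm <- with_seed_(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  bundle$split <- split
  bundle
}

#' Per-channel standardization statistics from the training split
#'
#' Computes, per channel, the mean and standard deviation over all time points
#' of the training-split epochs (all epochs if no split is assigned). These
#' statistics are applied to every split — the standard leakage-free recipe.
#'
#' @param bundle An `eeg_bundle`.
#' @return List with numeric vectors `mu` and `sd` (length `C`); `sd` entries
#'   below `1e-12` are clamped to 1 so flat channels pass through unscaled.
#' @export
channel_stats <- function(bundle) {
  idx <- split_indices(bundle, "train")
  if (length(idx) == 0L) idx <- seq_len(n_epochs(bundle))
  x <- bundle$signals[, , idx, drop = FALSE]
  C <- dim(x)[1L]
  xm <- matrix(x, nrow = C)
  mu <- rowMeans(xm)
  sd <- sqrt(rowMeans((xm - mu)^2))
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

#' Apply per-channel standardization
#'
#' @param bundle An `eeg_bundle`.
#' @param stats Statistics from [channel_stats()] (defaults to computing them
#'   from `bundle`'s training split).
#' @return The standardized bundle; the stats used are attached as
#'   `attr(, "channel_stats")`.
#' @export
standardize_bundle <- function(bundle, stats = channel_stats(bundle)) {
  d <- dim(bundle$signals)
  bundle$signals <- array((bundle$signals - stats$mu) / stats$sd, dim = d)
  attr(bundle, "channel_stats") <- stats
  bundle
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
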