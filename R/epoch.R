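#' Labeled EEG epoch
#'
#' An `eeg_epoch` is the universal input record of the package: one real-valued
#' channels-by-time signal array together with its label and metadata. Epochs
#' are labeled either with a binary fixation flag (fixation task) or with a 2-D
#' gaze point in screen coordinates (gaze regression task), never both.
#'
#' @param signal Numeric matrix, `C` channels by `L` time samples (microvolts).
#' @param channel_names Character vector of `C` unique electrode labels
#'   (10-20 system labels for real recordings; arbitrary for synthetic data).
#' @param sampling_rate Sampling rate in Hz.
#' @param label Either a single flag in `{0, 1}` (fixation) or a length-2
#'   numeric `(x, y)` gaze point in screen-coordinate units (mm).
#' @param label_type `"fixation"` or `"gaze"`; must be consistent with `label`.
#' @param subject_id Opaque subject identifier.
#' @param source_task One of `"angle_amplitude"`, `"absolute_position"`,
#'   `"synthetic"`.
#'
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(signal, channel_names, sampling_rate,
                      label, label_type = c("gaze", "fixation"),
                      subject_id = NA_character_,
                      source_task = c("synthetic", "angle_amplitude",
                                      "absolute_position")) {
  label_type <- match.arg(label_type)
  source_task <- match.arg(source_task)
  signal <- as.matrix(signal)
  obj <- structure(
    list(signal = signal, channel_names = as.character(channel_names),
         sampling_rate = sampling_rate, label = label,
         label_type = label_type, subject_id = subject_id,
         source_task = source_task),
    class = "eeg_epoch")
  validate_eeg_epoch(obj)
  obj
}

#' Validate an EEG epoch
#'
#' Enforces the epoch invariants: a finite `C x L` signal with `L >= 1`,
#' exactly `C` unique channel names, and exactly one of the two label kinds,
#' consistent with `label_type`.
#'
#' @param x An `eeg_epoch`.
#' @return `x`, invisibly; errors if any invariant is violated.
#' @export
validate_eeg_epoch <- function(x) {
  stopifnot(inherits(x, "eeg_epoch"))
  sig <- x$signal
  if (!is.matrix(sig) || !is.numeric(sig))
    stop("epoch signal must be a numeric C x L matrix")
  if (ncol(sig) < 1L) stop("epoch signal must have L >= 1 time samples")
  if (any(!is.finite(sig))) stop("epoch signal contains NaN/Inf values")
  nm <- x$channel_names
  if (length(nm) != nrow(sig))
    stop("channel_names length (", length(nm), ") != number of signal rows (",
         nrow(sig), ")")
  if (anyDuplicated(nm)) stop("channel_names must be unique")
  if (!is.numeric(x$sampling_rate) || x$sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (x$label_type == "fixation") {
    if (length(x$label) != 1L || !(x$label %in% c(0, 1)))
      stop("fixation label must be a single flag in {0, 1}")
  } else {
    if (length(x$label) != 2L || any(!is.finite(x$label)))
      stop("gaze label must be a finite (x, y) pair")
  }
  invisible(x)
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz, %s label (%s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              x$label_type, x$source_task))
  invisible(x)
}

#' Bundle of EEG epochs sharing one montage
#'
#' An `eeg_bundle` stores an ordered collection of epochs that share channel
#' count, length, channel names and sampling rate, as a single
#' `C x L x n` array, plus labels and an optional train/val/test split
#' assignment. It is the container every pipeline stage consumes and returns.
#'
#' @param signals Numeric array `C x L x n`.
#' @param channel_names Character vector of length `C`.
#' @param sampling_rate Hz.
#' @param labels For `label_type = "gaze"` an `n x 2` matrix of gaze points;
#'   for `"fixation"` a length-`n` vector of flags in `{0, 1}`.
#' @param label_type `"gaze"` or `"fixation"`.
#' @param source_task Provenance of the epochs.
#' @param subject_id Optional length-`n` vector of subject identifiers.
#' @param split Optional length-`n` character vector with values in
#'   `c("train", "val", "test")` (or `NA` before assignment).
#'
#' @return An object of class `eeg_bundle`.
#' @export
eeg_bundle <- function(signals, channel_names, sampling_rate,
                       labels, label_type = c("gaze", "fixation"),
                       source_task = c("synthetic", "angle_amplitude",
                                       "absolute_position"),
                       subject_id = NULL, split = NULL) {
  label_type <- match.arg(label_type)
  source_task <- match.arg(source_task)
  if (length(dim(signals)) != 3L)
    stop("signals must be a C x L x n array")
  n <- dim(signals)[3L]
  if (label_type == "gaze") {
    labels <- as.matrix(labels)
    if (ncol(labels) != 2L) stop("gaze labels must be an n x 2 matrix")
  } else {
    labels <- as.numeric(labels)
  }
  if (is.null(subject_id)) subject_id <- rep(NA_character_, n)
  if (is.null(split)) split <- rep(NA_character_, n)
  obj <- structure(
    list(signals = signals, channel_names = as.character(channel_names),
         sampling_rate = sampling_rate, labels = labels,
         label_type = label_type, source_task = source_task,
         subject_id = subject_id, split = split),
    class = "eeg_bundle")
  validate_eeg_bundle(obj)
  obj
}

#' Validate an EEG bundle
#'
#' @param x An `eeg_bundle`.
#' @return `x`, invisibly.
#' @export
validate_eeg_bundle <- function(x) {
  stopifnot(inherits(x, "eeg_bundle"))
  d <- dim(x$signals)
  if (length(d) != 3L) stop("signals must be a C x L x n array")
  if (d[2L] < 1L) stop("bundle epochs must have L >= 1 samples")
  if (any(!is.finite(x$signals))) stop("bundle signals contain NaN/Inf")
  if (length(x$channel_names) != d[1L])
    stop("channel_names length != channel dimension")
  if (anyDuplicated(x$channel_names)) stop("channel_names must be unique")
  n <- d[3L]
  nlab <- if (x$label_type == "gaze") nrow(x$labels) else length(x$labels)
  if (nlab != n)
    stop("label count (", nlab, ") != number of epochs (", n, ")")
  if (x$label_type == "fixation" && !all(x$labels %in% c(0, 1)))
    stop("fixation labels must be flags in {0, 1}")
  if (length(x$split) != n) stop("split assignment length != n")
  bad <- !is.na(x$split) & !(x$split %in% c("train", "val", "test"))
  if (any(bad)) stop("split values must be train/val/test")
  invisible(x)
}

#' Number of epochs in a bundle
#' @param bundle An `eeg_bundle`.
#' @return Integer count.
#' @export
n_epochs <- function(bundle) dim(bundle$signals)[3L]

#' Extract one epoch from a bundle
#' @param bundle An `eeg_bundle`.
#' @param i Epoch index.
#' @return An `eeg_epoch`.
#' @export
get_epoch <- function(bundle, i) {
  stopifnot(i >= 1L, i <= n_epochs(bundle))
  lab <- if (bundle$label_type == "gaze") bundle$labels[i, ] else
    bundle$labels[i]
  eeg_epoch(bundle$signals[, , i, drop = TRUE],
            bundle$channel_names, bundle$sampling_rate,
            label = lab, label_type = bundle$label_type,
            subject_id = bundle$subject_id[i],
            source_task = bundle$source_task)
}

#' Subset a bundle by epoch index
#' @param bundle An `eeg_bundle`.
#' @param idx Integer vector of epoch indices.
#' @return An `eeg_bundle` containing the selected epochs, in `idx` order.
#' @export
subset_epochs <- function(bundle, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_epochs(bundle)))
  labels <- if (bundle$label_type == "gaze") bundle$labels[idx, , drop = FALSE]
            else bundle$labels[idx]
  eeg_bundle(bundle$signals[, , idx, drop = FALSE], bundle$channel_names,
             bundle$sampling_rate, labels, bundle$label_type,
             bundle$source_task, bundle$subject_id[idx], bundle$split[idx])
}

#' Indices of epochs belonging to one split
#' @param bundle An `eeg_bundle` with a split assignment.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return Integer vector of epoch indices.
#' @export
split_indices <- function(bundle, split = c("train", "val", "test")) {
  split <- match.arg(split)
  which(!is.na(bundle$split) & bundle$split == split)
}

#' @export
print.eeg_bundle <- function(x, ...) {
  d <- dim(x$signals)
  spl <- if (all(is.na(x$split))) "unassigned" else
    paste(table(factor(x$split, c("train", "val", "test"))), collapse = "/")
  cat(sprintf("<eeg_bundle> %d epochs of %d x %d @ %g Hz, %s labels, splits %s\n",
              d[3], d[1], d[2], x$sampling_rate, x$label_type, spl))
  invisible(x)
}
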