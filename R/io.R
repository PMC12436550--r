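#' Write a bundle or dataset container to disk
#'
#' Bundles are stored in R's native serialization format. The same container
#' is used for raw dataset exchange: a plain list holding a 3-D signal array,
#' labels, channel names, sampling rate and an explicit orientation flag
#' saying whether the array is `(n, C, L)` or `(n, L, C)`.
#'
#' @param bundle An `eeg_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_eeg_bundle(bundle)
  saveRDS(bundle, path)
  invisible(path)
}

#' Read a bundle written by [write_bundle()]
#' @param path File path.
#' @return An `eeg_bundle`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  b <- readRDS(path)
  validate_eeg_bundle(b)
  b
}

#' Write a raw dataset container
#'
#' @param path Output path.
#' @param signals 3-D array, `(n, C, L)` or `(n, L, C)` per `orientation`.
#' @param labels Length-`n` fixation flags or `n x 2` gaze matrix.
#' @param channel_names Length-`C` labels.
#' @param sampling_rate Hz.
#' @param orientation `"ncl"` if `signals` is `(n, C, L)`, `"nlc"` if
#'   `(n, L, C)`.
#' @return `path`, invisibly.
#' @export
write_dataset_container <- function(path, signals, labels, channel_names,
                                    sampling_rate,
                                    orientation = c("ncl", "nlc")) {
  orientation <- match.arg(orientation)
  stopifnot(length(dim(signals)) == 3L)
  saveRDS(list(signals = signals, labels = labels,
               channel_names = as.character(channel_names),
               sampling_rate = sampling_rate, orientation = orientation),
          path)
  invisible(path)
}

#' Load a labeled dataset from a container file
#'
#' Reads a container written by [write_dataset_container()] (or an already
#' serialized `eeg_bundle`) and normalizes the signal orientation to
#' channels-by-time. The two stored orientations `(n, C, L)` and `(n, L, C)`
#' yield identical bundles.
#'
#' @param path File path.
#' @param task Label semantics of the container: `"gaze"` or `"fixation"`.
#' @param source_task Provenance tag for the resulting bundle.
#' @return An `eeg_bundle` of `n` epochs, each `C x L`.
#' @export
load_dataset <- function(path, task = c("gaze", "fixation"),
                         source_task = c("synthetic", "angle_amplitude",
                                         "absolute_position")) {
  task <- match.arg(task)
  source_task <- match.arg(source_task)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readRDS(path)
  if (inherits(raw, "eeg_bundle")) {
    validate_eeg_bundle(raw)
    return(raw)
  }
  need <- c("signals", "labels", "channel_names", "sampling_rate",
            "orientation")
  if (!all(need %in% names(raw)))
    stop("container is missing fields: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  sig <- raw$signals
  d <- dim(sig)
  if (length(d) != 3L) stop("container signals must be a 3-D array")
  C <- length(raw$channel_names)
  # normalize to C x L x n
  sig <- if (raw$orientation == "ncl") aperm(sig, c(2, 3, 1))
         else aperm(sig, c(3, 2, 1))
  if (dim(sig)[1L] != C)
    stop("shape mismatch: container declares C = ", C,
         " channels but signals have ", dim(sig)[1L],
         " under orientation '", raw$orientation, "'")
  n <- dim(sig)[3L]
  nlab <- if (task == "gaze") nrow(as.matrix(raw$labels)) else
    length(raw$labels)
  if (nlab != n)
    stop("label array length (", nlab, ") != number of signals (", n, ")")
  eeg_bundle(sig, raw$channel_names, raw$sampling_rate, raw$labels,
             label_type = task, source_task = source_task)
}

#' Read an external split manifest
#'
#' A split manifest is a two-column CSV (`epoch_id`, `split`) carrying an
#' externally provided train/val/test assignment, e.g. a benchmark's own
#' subject-respecting partition.
#'
#' @param path CSV path.
#' @return Data frame with columns `epoch_id`, `split`.
#' @export
read_split_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_id", "split") %in% colnames(m)))
    stop("manifest must have columns epoch_id, split")
  if (!all(m$split %in% c("train", "val", "test")))
    stop("manifest split values must be train/val/test")
  m
}

#' Apply a split manifest to a bundle
#'
#' @param bundle An `eeg_bundle`.
#' @param manifest Data frame from [read_split_manifest()]; `epoch_id` indexes
#'   epochs (1-based).
#' @return The bundle with `split` set from the manifest.
#' @export
apply_split_manifest <- function(bundle, manifest) {
  ids <- as.integer(manifest$epoch_id)
  if (any(ids < 1L) || any(ids > n_epochs(bundle)))
    stop("manifest epoch_id out of range")
  bundle$split[ids] <- manifest$split
  validate_eeg_bundle(bundle)
  bundle
}
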