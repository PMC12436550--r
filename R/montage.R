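#' Electrode montage
#'
#' A montage is an ordered set of electrode names, optionally with 2-D scalp
#' coordinates on a unit-disc head projection (nose up, right ear at x > 0).
#' Montages define channel subsets: [select_channels()] restricts an epoch or
#' bundle to a montage's channels, in montage order.
#'
#' @param names Character vector of unique electrode labels.
#' @param positions Optional data frame with columns `x`, `y`, one row per
#'   label, on the unit disc.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(names, positions = NULL) {
  names <- as.character(names)
  if (anyDuplicated(tolower(names))) stop("montage names must be unique")
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    if (!all(c("x", "y") %in% colnames(positions)))
      stop("positions must have columns x and y")
    if (nrow(positions) != length(names))
      stop("positions must have one row per montage name")
  }
  structure(list(names = names, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes%s: %s\n", length(x$names),
              if (is.null(x$positions)) "" else " (with positions)",
              paste(utils::head(x$names, 10), collapse = ", ")))
  invisible(x)
}

# Approximate unit-disc 10-20 coordinates for the labels the package ships.
# Radial placement follows the conventional 10-20 angular layout; good enough
# for topographic display, not for source modelling.
.positions_1020 <- data.frame(
  name = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
           "T7", "C3", "Cz", "C4", "T8",
           "P7", "P3", "Pz", "P4", "P8",
           "PO7", "PO3", "POz", "PO4", "PO8",
           "O1", "Oz", "O2"),
  x = c(-0.31, 0.31, -0.81, -0.41, 0.00, 0.41, 0.81,
        -1.00, -0.50, 0.00, 0.50, 1.00,
        -0.81, -0.41, 0.00, 0.41, 0.81,
        -0.59, -0.30, 0.00, 0.30, 0.59,
        -0.31, 0.00, 0.31),
  y = c(0.95, 0.95, 0.59, 0.48, 0.50, 0.48, 0.59,
        0.00, 0.00, 0.00, 0.00, 0.00,
        -0.59, -0.48, -0.50, -0.48, -0.59,
        -0.81, -0.73, -0.75, -0.73, -0.81,
        -0.95, -1.00, -0.95),
  stringsAsFactors = FALSE)

#' Standard 10-20 montage for a set of labels
#'
#' Builds a montage with approximate unit-disc scalp positions for labels of
#' the standardized 10-20 system known to the package. Matching is
#' case-insensitive; unknown labels get no position.
#'
#' @param names Electrode labels.
#' @return An `eeg_montage`; `positions` is `NULL` if no label is known.
#' @export
montage_1020 <- function(names) {
  idx <- match(tolower(names), tolower(.positions_1020$name))
  if (all(is.na(idx))) return(montage(names))
  pos <- data.frame(x = .positions_1020$x[idx], y = .positions_1020$y[idx])
  montage(names, pos)
}

#' The consumer-grade 8-electrode reduced montage
#'
#' The channel subset used for the channel-reduction protocol: the eight
#' electrodes of a consumer-grade headset (7 plus a reference one), selected
#' from the high-density cap for comparison against the full 129-channel
#' system.
#'
#' @return An `eeg_montage` of the 8 electrodes
#'   `Fz, Cz, C3, C4, Pz, Oz, PO7, PO8`, with unit-disc positions.
#' @export
reduced_montage <- function() {
  montage_1020(c("Fz", "Cz", "C3", "C4", "Pz", "Oz", "PO7", "PO8"))
}

#' Nominal epoch geometry of the benchmark recordings
#'
#' The benchmark's epochs are 1-second windows sampled at 500 Hz from a
#' 129-electrode cap (128 plus reference), giving `L = 500` samples and
#' `C = 129` channels per epoch.
#'
#' @param duration_s Epoch duration in seconds.
#' @param sampling_rate Hz.
#' @param n_channels Electrode count.
#' @return List with `C`, `L`, `sampling_rate`, `duration_s`.
#' @export
nominal_epoch_geometry <- function(duration_s = 1, sampling_rate = 500,
                                   n_channels = 129) {
  list(C = as.integer(n_channels),
       L = as.integer(round(duration_s * sampling_rate)),
       sampling_rate = sampling_rate, duration_s = duration_s)
}
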