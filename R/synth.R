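#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the data regime the decoders are designed for:
#' multichannel epochs in which a small set of planted channels carries
#' gaze-informative structure inside a centrally localized temporal window,
#' on top of 1/f-like background noise, with a configurable ~45/55 class
#' balance for the fixation task. Desk-scale defaults (`C = 16`, `L = 128`)
#' keep every downstream experiment runnable on one CPU; the nominal
#' `129 x 500` geometry is available by passing it explicitly.
#'
#' Gaze labels are encoded in the amplitudes of two Hann-windowed oscillatory
#' bursts placed on the planted channels: a 10 Hz burst at the left flank of
#' the informative window encodes the x coordinate and a 25 Hz burst at the
#' right flank encodes y, each through an affine, invertible amplitude map.
#' Because the bursts sit at the window flanks, central cropping that retains
#' the window keeps both bursts, while cropping beyond it removes them
#' entirely — the cropping rationale at a literally testable scale.
#'
#' @param n_epochs Number of epochs.
#' @param C,L Channel count and epoch length in samples.
#' @param sampling_rate Hz (default 128: 1-second epochs).
#' @param planted_channels Indices of the gaze-informative channels.
#' @param informative_window Center fraction of `L` carrying signal, in
#'   `(0, 1]`.
#' @param noise_sigma Background noise standard deviation (microvolts).
#' @param task `"gaze"` or `"fixation"`.
#' @param class_balance Positive (fixation) fraction for the fixation task.
#' @param gaze_range List with `x` and `y` coordinate bounds (mm).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_epochs = 600, C = 16, L = 128, sampling_rate = 128,
                         planted_channels = c(3, 8, 13),
                         informative_window = 0.5, noise_sigma = 1,
                         task = c("gaze", "fixation"), class_balance = 0.45,
                         gaze_range = list(x = c(0, 800), y = c(0, 600)),
                         seed = 1L) {
  task <- match.arg(task)
  planted_channels <- as.integer(planted_channels)
  if (length(planted_channels) &&
      (any(planted_channels < 1L) || any(planted_channels > C)))
    stop("planted_channels must lie in [1, C]")
  if (informative_window <= 0 || informative_window > 1)
    stop("informative_window must lie in (0, 1]")
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must lie in (0, 1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_epochs = as.integer(n_epochs), C = as.integer(C),
                 L = as.integer(L), sampling_rate = sampling_rate,
                 planted_channels = planted_channels,
                 informative_window = informative_window,
                 noise_sigma = noise_sigma, task = task,
                 class_balance = class_balance, gaze_range = gaze_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Planted-channel ground truth
#'
#' The oracle the channel-recovery tests assert against: which channels
#' actually carry the gaze signal, straight from the configuration.
#'
#' @param config A `synth_config`.
#' @return Integer vector of planted channel indices.
#' @export
planted_channel_ground_truth <- function(config) config$planted_channels

# Burst carrier frequencies (Hz): alpha-band for x, beta-band for y.
.f_x <- 10
.f_y <- 25

# Time-index supports of the two label-carrying bursts, in original sample
# coordinates. The informative window is the central fraction `w` of L; each
# burst occupies a stretch of length floor(0.2 * w * L) at one flank.
burst_supports <- function(config) {
  L <- config$L; w <- config$informative_window
  i0 <- floor((0.5 - w / 2) * L) + 1L
  i1 <- floor((0.5 + w / 2) * L)
  blen <- max(4L, floor(0.2 * w * L))
  list(window = i0:i1,
       x = i0:(i0 + blen - 1L),
       y = (i1 - blen + 1L):i1)
}

# Hann-windowed sinusoid of unit amplitude over `idx` (original coordinates).
burst_wave <- function(idx, freq, fs) {
  tau <- seq_along(idx) - 1L
  hann <- 0.5 * (1 - cos(2 * pi * tau / (length(idx) - 1)))
  hann * sin(2 * pi * freq * tau / fs)
}

# Amplitude map: coordinate normalized to [0,1] -> burst amplitude in uV.
# Affine and strictly increasing, hence invertible.
.amp_base <- 2
.amp_gain <- 8
amp_of <- function(z, lo, hi) .amp_base + .amp_gain * (z - lo) / (hi - lo)

# 1/f-like background noise: white spectrum shaped by 1/sqrt(f) above the
# first bin, zero DC, rescaled to the requested standard deviation.
pink_noise <- function(L, n, sd_target, fs) {
  if (sd_target == 0) return(matrix(0, L, n))
  white <- matrix(stats::rnorm(L * n), L, n)
  k <- 0:(L - 1)
  f <- pmin(k, L - k) * fs / L
  scale <- 1 / sqrt(pmax(f, fs / L))
  scale[1] <- 0
  x <- Re(stats::mvfft(stats::mvfft(white) * scale, inverse = TRUE)) / L
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  x * sd_target
}

synth_channel_names <- function(C) sprintf("S%02d", seq_len(C))

#' Generate a synthetic gaze-regression dataset
#'
#' Labels are drawn uniformly from `gaze_range`; each planted channel carries
#' the two label-encoding bursts described in [synth_config()] on top of the
#' background noise. Deterministic given the config (including its seed), and
#' split 70/15/15 by the same seed.
#'
#' @param config A `synth_config` with `task = "gaze"`.
#' @return An `eeg_bundle` with gaze labels and split assignment.
#' @export
generate_gaze_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$task != "gaze") stop("config task must be 'gaze'")
  sup <- burst_supports(config)
  wx <- burst_wave(sup$x, .f_x, config$sampling_rate)
  wy <- burst_wave(sup$y, .f_y, config$sampling_rate)
  rx <- config$gaze_range$x; ry <- config$gaze_range$y
  with_seed_(config$seed, {
    n <- config$n_epochs
    labx <- stats::runif(n, rx[1], rx[2])
    laby <- stats::runif(n, ry[1], ry[2])
    signals <- array(0, dim = c(config$C, config$L, n))
    for (i in seq_len(n)) {
      bg <- t(pink_noise(config$L, config$C, config$noise_sigma,
                         config$sampling_rate))
      if (length(config$planted_channels)) {
        ax <- amp_of(labx[i], rx[1], rx[2])
        ay <- amp_of(laby[i], ry[1], ry[2])
        bg[config$planted_channels, sup$x] <-
          bg[config$planted_channels, sup$x, drop = FALSE] +
          matrix(ax * wx, length(config$planted_channels), length(wx),
                 byrow = TRUE)
        bg[config$planted_channels, sup$y] <-
          bg[config$planted_channels, sup$y, drop = FALSE] +
          matrix(ay * wy, length(config$planted_channels), length(wy),
                 byrow = TRUE)
      }
      signals[, , i] <- bg
    }
    b <- eeg_bundle(signals, synth_channel_names(config$C),
                    config$sampling_rate, cbind(x = labx, y = laby),
                    label_type = "gaze", source_task = "synthetic")
    split_dataset(b, seed = config$seed)
  })
}

#' Generate a synthetic fixation-classification dataset
#'
#' Positive epochs (fixation) contain background noise only; negative epochs
#' (saccadic, non-fixation) additionally carry a triangular ramp transient
#' spanning the informative window on the planted channels — an idealized
#' saccade deflection. The positive fraction matches `class_balance` within
#' one epoch.
#'
#' @param config A `synth_config` with `task = "fixation"`.
#' @return An `eeg_bundle` with fixation labels and split assignment.
#' @export
generate_fixation_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$task != "fixation") stop("config task must be 'fixation'")
  sup <- burst_supports(config)
  win <- sup$window
  m <- length(win)
  ramp <- 1 - abs(seq(-1, 1, length.out = m))  # triangular, peak at center
  ramp_amp <- .amp_base + .amp_gain / 2
  with_seed_(config$seed, {
    n <- config$n_epochs
    n_pos <- round(config$class_balance * n)
    labels <- sample(c(rep(1, n_pos), rep(0, n - n_pos)))
    signals <- array(0, dim = c(config$C, config$L, n))
    for (i in seq_len(n)) {
      bg <- t(pink_noise(config$L, config$C, config$noise_sigma,
                         config$sampling_rate))
      if (labels[i] == 0 && length(config$planted_channels)) {
        bg[config$planted_channels, win] <-
          bg[config$planted_channels, win, drop = FALSE] +
          matrix(ramp_amp * ramp, length(config$planted_channels), m,
                 byrow = TRUE)
      }
      signals[, , i] <- bg
    }
    b <- eeg_bundle(signals, synth_channel_names(config$C),
                    config$sampling_rate, labels,
                    label_type = "fixation", source_task = "synthetic")
    split_dataset(b, seed = config$seed)
  })
}

#' Quadrature band-power features of the planted bursts
#'
#' The independent decodability oracle: for every planted channel, the sine
#' and cosine projections of the signal onto the x-burst carrier (10 Hz, left
#' flank) and the y-burst carrier (25 Hz, right flank). The feature map is
#' linear in the signal, so with zero noise an ordinary-least-squares fit on
#' these features recovers the labels exactly. Works on cropped bundles: the
#' supports are intersected with the retained samples (empty intersection
#' yields a zero-column block — no information survives the crop).
#'
#' @param bundle An `eeg_bundle` generated from `config` (possibly cropped).
#' @param config The generating `synth_config`.
#' @return Numeric matrix, one row per epoch.
#' @export
oracle_gaze_features <- function(bundle, config) {
  sup <- burst_supports(config)
  Lcur <- dim(bundle$signals)[2L]
  offset <- (config$L - Lcur) %/% 2L  # symmetric central crop
  feats <- NULL
  for (part in list(list(idx = sup$x, f = .f_x),
                    list(idx = sup$y, f = .f_y))) {
    keep <- part$idx[part$idx > offset & part$idx <= offset + Lcur]
    if (length(keep) == 0L) next
    tau <- keep - part$idx[1L]
    s <- sin(2 * pi * part$f * tau / config$sampling_rate)
    co <- cos(2 * pi * part$f * tau / config$sampling_rate)
    for (ch in config$planted_channels) {
      seg <- bundle$signals[ch, keep - offset, , drop = TRUE]
      seg <- matrix(seg, nrow = length(keep))
      feats <- cbind(feats, colSums(seg * s), colSums(seg * co))
    }
  }
  if (is.null(feats)) feats <- matrix(0, n_epochs(bundle), 0)
  feats
}

#' Least-squares decodability oracle for synthetic gaze data
#'
#' Fits ordinary least squares from the [oracle_gaze_features()] of the
#' training split to the gaze labels and reports test-split RMSE/MAE (the
#' package's 1/(2n) conventions). This defines what "decodable" means for the
#' generator; it never touches the neural models.
#'
#' @param bundle A synthetic gaze `eeg_bundle` with split assignment.
#' @param config The generating `synth_config`.
#' @return List with `rmse`, `mae`, and `label_sd` (pooled over x and y).
#' @export
oracle_gaze_decode <- function(bundle, config) {
  feats <- oracle_gaze_features(bundle, config)
  tr <- split_indices(bundle, "train"); te <- split_indices(bundle, "test")
  y_tr <- bundle$labels[tr, , drop = FALSE]
  y_te <- bundle$labels[te, , drop = FALSE]
  if (ncol(feats) == 0L) {
    pred <- matrix(colMeans(y_tr), length(te), 2, byrow = TRUE)
  } else {
    X_tr <- feats[tr, , drop = FALSE]; X_te <- feats[te, , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X_tr), y_tr)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, X_te) %*% beta
  }
  m <- evaluate_regression(y_te, pred)
  list(rmse = m$rmse, mae = m$mae,
       label_sd = stats::sd(as.numeric(bundle$labels)))
}

#' Ramp-energy separator for synthetic fixation data
#'
#' Closed-form oracle for the fixation generator: the mean signal of the
#' planted channels over the informative window, which is elevated by the
#' ramp transient in negative (saccade) epochs. Thresholding this statistic
#' at the midpoint separates the classes perfectly when `noise_sigma = 0`.
#'
#' @param bundle A synthetic fixation `eeg_bundle` (possibly cropped).
#' @param config The generating `synth_config`.
#' @return Numeric vector of per-epoch ramp scores.
#' @export
oracle_fixation_score <- function(bundle, config) {
  sup <- burst_supports(config)
  Lcur <- dim(bundle$signals)[2L]
  offset <- (config$L - Lcur) %/% 2L
  keep <- sup$window[sup$window > offset & sup$window <= offset + Lcur]
  if (length(keep) == 0L) return(rep(0, n_epochs(bundle)))
  seg <- bundle$signals[config$planted_channels, keep - offset, ,
                        drop = FALSE]
  apply(seg, 3, mean)
}
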