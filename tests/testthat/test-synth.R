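test_that("generators are deterministic and expose planted ground truth", {
  sc <- synth_config(n_epochs = 20, task = "gaze", seed = 5)
  b1 <- generate_gaze_dataset(sc)
  b2 <- generate_gaze_dataset(sc)
  expect_identical(b1, b2)
  expect_equal(planted_channel_ground_truth(sc), c(3L, 8L, 13L))
  sc2 <- synth_config(n_epochs = 50, planted_channels = c(3, 17), C = 20)
  expect_equal(planted_channel_ground_truth(sc2), c(3L, 17L))
  # ground truth does not depend on the epoch count
  sc3 <- synth_config(n_epochs = 999, planted_channels = c(3, 17), C = 20)
  expect_equal(planted_channel_ground_truth(sc3),
               planted_channel_ground_truth(sc2))

  expect_error(synth_config(planted_channels = 99), "planted_channels")
  expect_error(synth_config(informative_window = 0), "informative_window")
  expect_error(synth_config(class_balance = 1), "class_balance")
})

test_that("generated bundles satisfy the epoch invariants", {
  for (task in c("gaze", "fixation")) {
    sc <- synth_config(n_epochs = 12, task = task, seed = 2)
    b <- if (task == "gaze") generate_gaze_dataset(sc)
         else generate_fixation_dataset(sc)
    expect_silent(validate_eeg_bundle(b))
    expect_equal(dim(b$signals), c(16, 128, 12))
    expect_false(anyNA(b$split))
  }
})

test_that("noiseless gaze labels are exactly recoverable by the OLS oracle", {
  sc <- synth_config(n_epochs = 120, noise_sigma = 0, task = "gaze",
                     seed = 8)
  b <- generate_gaze_dataset(sc)
  orc <- oracle_gaze_decode(b, sc)
  range_scale <- diff(sc$gaze_range$x)
  expect_lt(orc$rmse, 0.01 * range_scale)
})

test_that("without planted channels the constant predictor is optimal", {
  sc <- synth_config(n_epochs = 150, planted_channels = integer(0),
                     task = "gaze", seed = 9)
  b <- generate_gaze_dataset(sc)
  orc <- oracle_gaze_decode(b, sc)
  # no informative features: oracle cannot beat the label dispersion
  expect_gt(orc$rmse, 0.95 * constant_baseline(b, "test")$rmse)
})

test_that("fixation generator hits the class balance and is separable", {
  sc <- synth_config(n_epochs = 1000, task = "fixation", seed = 3)
  b <- generate_fixation_dataset(sc)
  expect_equal(sum(b$labels == 1), 450)

  sc0 <- synth_config(n_epochs = 80, task = "fixation", noise_sigma = 0,
                      seed = 4)
  b0 <- generate_fixation_dataset(sc0)
  score <- oracle_fixation_score(b0, sc0)
  # ramp energy separates the classes perfectly at sigma = 0
  thr <- mean(range(score))
  expect_true(all((score > thr) == (b0$labels == 0)))
})

test_that("background noise has a 1/f-like spectrum", {
  set.seed(10)
  x <- eegaze:::pink_noise(1024, 50, 1, 128)
  spec <- Mod(stats::mvfft(x))^2
  f <- (0:1023) * 128 / 1024
  band <- which(f >= 2 & f <= 40)
  fit <- lm(log(rowMeans(spec)[band]) ~ log(f[band]))
  expect_lt(abs(coef(fit)[2] + 1), 0.35)
  expect_equal(apply(x, 2, sd), rep(1, 50), tolerance = 1e-8)
})

test_that("cropping that retains the informative window preserves oracle
           decodability; cropping beyond it destroys it", {
  sc <- synth_config(n_epochs = 150, noise_sigma = 0, task = "gaze",
                     seed = 12)
  b <- generate_gaze_dataset(sc)
  # window is the central 50%: rho = 0.2 keeps it entirely
  orc_keep <- oracle_gaze_decode(crop_signal(b, 0.2), sc)
  expect_lt(orc_keep$rmse, 0.01 * diff(sc$gaze_range$x))
  # rho = 0.4 retains only the central 20%: both burst supports are gone
  orc_gone <- oracle_gaze_decode(crop_signal(b, 0.4), sc)
  expect_gt(orc_gone$rmse, 0.8 * orc_gone$label_sd)
})
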