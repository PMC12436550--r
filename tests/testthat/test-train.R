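micro_gaze_bundle <- function(n = 60, seed = 21) {
  sc <- synth_config(n_epochs = n, C = 8, L = 16, sampling_rate = 16,
                     planted_channels = c(2, 5), informative_window = 1,
                     noise_sigma = 0.5, task = "gaze", seed = seed)
  generate_gaze_dataset(sc)
}

micro_cfg <- function(head = "gaze") {
  model_config("model_b", C = 8, L = 16, K = 4, H = 6, n_blocks = 2,
               transformer_layers = 1, transformer_heads = 2, head = head,
               sampling_rate = 16)
}

test_that("training is reproducible and validates its inputs", {
  b <- micro_gaze_bundle()
  tc <- train_config("gaze", epochs = 2, seed = 5)
  f1 <- train_model(b, micro_cfg(), tc)
  f2 <- train_model(b, micro_cfg(), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)

  expect_error(train_model(b, micro_cfg("fixation"),
                           train_config("fixation", epochs = 1)),
               "labels are gaze")
  expect_error(train_model(b, micro_cfg(), train_config("fixation")),
               "disagree")
  b_nosplit <- b; b_nosplit$split[] <- NA_character_
  expect_error(train_model(b_nosplit, micro_cfg(),
                           train_config("gaze", epochs = 1)),
               "no training epochs")
  expect_error(train_config("gaze", epochs = 0), "epochs")
})

test_that("one epoch of training decreases the loss on decodable data", {
  sc <- synth_config(n_epochs = 80, C = 8, L = 16, sampling_rate = 16,
                     planted_channels = c(2, 5), informative_window = 1,
                     noise_sigma = 0, task = "gaze", seed = 31)
  b <- generate_gaze_dataset(sc)
  fit <- train_model(b, micro_cfg(), train_config("gaze", epochs = 3,
                                                  seed = 2))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("shuffled labels yield chance-level accuracy", {
  sc <- synth_config(n_epochs = 120, C = 8, L = 16, sampling_rate = 16,
                     planted_channels = c(2, 5), informative_window = 1,
                     noise_sigma = 1, task = "fixation",
                     class_balance = 0.5, seed = 41)
  b <- generate_fixation_dataset(sc)
  set.seed(77)
  b$labels <- sample(b$labels)
  fit <- train_model(b, micro_cfg("fixation"),
                     train_config("fixation", epochs = 3, seed = 1))
  m <- evaluate_model(fit$model, b, "test")
  expect_gt(m$accuracy, 0.2)
  expect_lt(m$accuracy, 0.8)
})

test_that("prediction applies stored channel and label statistics", {
  b <- micro_gaze_bundle()
  fit <- train_model(b, micro_cfg(), train_config("gaze", epochs = 2,
                                                  seed = 9))
  expect_false(is.null(fit$model$norm_stats))
  expect_false(is.null(fit$model$label_stats))
  pred <- predict_bundle(fit$model, b, indices = 1:4)
  expect_equal(dim(pred$output), c(4L, 2L))
  # outputs are on the label scale, not the z-scored training scale
  expect_gt(mean(abs(pred$output)), 1)
})

test_that("multi-seed experiments store per-seed values with mean and sd", {
  b <- micro_gaze_bundle(n = 40)
  res <- multi_seed_experiment(b, micro_cfg(),
                               train_config("gaze", epochs = 1, seed = 1),
                               n_seeds = 3,
                               condition = list(rho = 0, montage = "full"))
  expect_s3_class(res, "run_result")
  expect_setequal(res$metric, c("RMSE", "MAE"))
  seed_cols <- paste0("seed", 1:3)
  expect_true(all(seed_cols %in% colnames(res)))
  for (r in seq_len(nrow(res))) {
    vals <- as.numeric(res[r, seed_cols])
    expect_equal(res$mean[r], mean(vals), tolerance = 1e-12)
    # sample (n-1) convention, recomputed by the one-pass formula
    one_pass <- sqrt((sum(vals^2) - length(vals) * mean(vals)^2) /
                       (length(vals) - 1))
    expect_equal(res$sd[r], one_pass, tolerance = 1e-9)
  }
  expect_error(multi_seed_experiment(b, micro_cfg(), n_seeds = 1), ">= 2")
})
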