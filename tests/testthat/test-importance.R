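random_row_stochastic <- function(S, Tn, seed = 1) {
  set.seed(seed)
  arr <- array(0, c(S, S, Tn))
  for (t in seq_len(Tn)) {
    M <- matrix(rexp(S * S), S, S)
    arr[, , t] <- M / rowSums(M)
  }
  arr
}

test_that("CLS-row extraction drops the self-attention column", {
  uni <- array(1 / 5, c(5, 5, 3))
  rows <- extract_cls_attention(uni)
  expect_equal(dim(rows), c(3L, 4L))
  expect_true(all(rows == 0.2))

  onehot <- array(0, c(5, 5, 2))
  onehot[1, 4, ] <- 1      # CLS attends entirely to channel 3
  onehot[2:5, , ] <- 1 / 5
  expect_equal(extract_cls_attention(onehot)[1, ], c(0, 0, 1, 0))

  arr <- random_row_stochastic(7, 4)
  rows <- extract_cls_attention(arr)
  for (t in 1:4)
    expect_equal(sum(rows[t, ]), 1 - arr[1, 1, t], tolerance = 1e-12)

  expect_error(extract_cls_attention(array(0, c(3, 4, 2))), "square")
  expect_error(extract_cls_attention(list(matrix(0, 3, 3),
                                          matrix(0, 4, 4))), "equally sized")
})

test_that("importance is the mean over segments, then over instances", {
  a <- c(0.1, 0.3, 0.2, 0.15)
  expect_equal(instance_importance(rbind(a, a)), a)
  expect_equal(instance_importance(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(2)
  M <- matrix(runif(40), 10, 4)
  expect_equal(instance_importance(M), colMeans(M), tolerance = 1e-12)

  expect_equal(aggregate_importance(rbind(a))$alpha, a)
  two <- aggregate_importance(rbind(c(1, 0), c(0, 1)))
  expect_equal(two$alpha, c(0.5, 0.5))
  P <- matrix(runif(300), 100, 3)
  expect_equal(aggregate_importance(P)$alpha, colMeans(P),
               tolerance = 1e-12)
  expect_error(aggregate_importance(list(c(1, 0), c(1, 0, 0))),
               "inconsistent")
})

test_that("segment/instance averaging is linear: grand mean equivalence", {
  set.seed(3)
  m <- 6; Tn <- 5; C <- 4
  all_rows <- NULL
  per_inst <- matrix(0, m, C)
  for (i in seq_len(m)) {
    rows <- matrix(runif(Tn * C), Tn, C)
    per_inst[i, ] <- instance_importance(rows)
    all_rows <- rbind(all_rows, rows)
  }
  agg <- aggregate_importance(per_inst)
  expect_equal(agg$alpha, colMeans(all_rows), tolerance = 1e-12)
})

test_that("top-fraction selection counts, orders, and breaks ties", {
  alpha <- runif(128)
  imp <- aggregate_importance(rbind(alpha))
  expect_length(top_fraction_channels(imp, 0.25), 32)
  all_ch <- top_fraction_channels(imp, 1)
  expect_length(all_ch, 128)
  expect_true(all(diff(alpha[all_ch]) <= 0))

  tied <- aggregate_importance(rbind(c(0.2, 0.5, 0.2, 0.5, 0.1)))
  expect_equal(unname(top_fraction_channels(tied, 0.8)), c(2, 4, 1, 3))
  expect_error(top_fraction_channels(imp, 0), "fraction")
  expect_error(top_fraction_channels(imp, 1.2), "fraction")
})

test_that("attention mass is conserved end to end on a live model", {
  cfg <- tiny_config("model_b", C = 6)
  m <- init_model(cfg, seed = 13)
  sc <- synth_config(n_epochs = 8, C = 6, L = 16, sampling_rate = 16,
                     planted_channels = c(2, 4), informative_window = 1,
                     task = "gaze", seed = 3)
  b <- generate_gaze_dataset(sc)
  imp <- compute_importance(m, b, "test")
  expect_true(all(imp$alpha >= 0 & imp$alpha <= 1))
  expect_lte(sum(imp$alpha), 1 + 1e-6)
  expect_equal(sum(imp$alpha) + imp$cls_self_mass, 1, tolerance = 1e-6)
  expect_equal(imp$n_segments, cfg$T_len)
})

test_that("topomap export writes a ranking CSV and falls back gracefully", {
  alpha <- c(Fz = 0.3, Cz = 0.2, Pz = 0.1)
  imp <- aggregate_importance(rbind(unname(alpha)),
                              montage = montage_1020(names(alpha)))
  png_path <- tempfile(fileext = ".png")
  paths <- export_topomap(imp, png_path)
  ranked <- read.csv(paths$csv)
  expect_equal(ranked$channel, c("Fz", "Cz", "Pz"))
  expect_equal(ranked$rank, 1:3)
  # identical input, identical CSV bytes
  paths2 <- export_topomap(imp, tempfile(fileext = ".png"))
  expect_identical(readBin(paths$csv, "raw", file.size(paths$csv)),
                   readBin(paths2$csv, "raw", file.size(paths2$csv)))

  bare <- aggregate_importance(rbind(unname(alpha)),
                               montage = montage(names(alpha)))
  expect_warning(out <- export_topomap(bare, tempfile(fileext = ".png")),
                 "positions")
  expect_true(file.exists(out$csv))
  expect_true(is.na(out$png))
})
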