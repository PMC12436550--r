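test_that("central cropping follows the floor(rho*L) rule", {
  e <- get_epoch(tiny_bundle(n = 1, C = 2, L = 500), 1)
  expect_identical(crop_signal(e, 0)$signal, e$signal)
  # rho = 0.3 keeps the central gamma = 0.4 of the signal: exactly 200
  expect_equal(ncol(crop_signal(e, 0.3)$signal), 200)

  e10 <- get_epoch(tiny_bundle(n = 1, C = 2, L = 10), 1)
  c10 <- crop_signal(e10, 0.1)
  expect_equal(ncol(c10$signal), 8)
  expect_identical(c10$signal, e10$signal[, 2:9])

  expect_error(crop_signal(e, 0.5), "0.5")
  expect_error(crop_signal(e, -0.1), "0.5")
})

test_that("cropping properties: length law, composition, label safety", {
  for (L in c(7, 64, 100, 500)) for (rho in c(0, 0.05, 0.1, 0.25, 0.3)) {
    b <- tiny_bundle(n = 2, C = 3, L = L)
    bc <- crop_signal(b, rho)
    m <- floor(rho * L)
    expect_equal(dim(bc$signals)[2], L - 2 * m)
    gamma <- 1 - 2 * rho
    expect_lt(abs(dim(bc$signals)[2] - gamma * L), 2)
    # labels and channel order untouched
    expect_identical(bc$labels, b$labels)
    expect_identical(bc$channel_names, b$channel_names)
    # cropping again with rho = 0 is the identity
    expect_identical(crop_signal(bc, 0)$signals, bc$signals)
  }
})

test_that("channel selection matches case-insensitively in montage order", {
  b <- tiny_bundle(n = 3, C = 4)
  full <- montage(b$channel_names)
  expect_identical(select_channels(b, full)$signals, b$signals)

  rev_m <- montage(tolower(rev(b$channel_names)))
  sel <- select_channels(b, rev_m)
  expect_identical(sel$signals[4, , ], b$signals[1, , ])
  expect_identical(sel$channel_names, rev(b$channel_names))
  # idempotent: selecting again with the same montage changes nothing
  expect_identical(select_channels(sel, rev_m)$signals, sel$signals)

  expect_error(select_channels(b, montage(c("CH01", "XX99"))), "XX99")
})

test_that("the reduced montage has the 8 consumer-headset electrodes", {
  rm <- reduced_montage()
  expect_length(rm$names, 8)
  expect_setequal(tolower(rm$names),
                  tolower(c("Fz", "Cz", "C3", "C4", "Pz", "OZ", "PO7",
                            "PO8")))
  expect_equal(nrow(rm$positions), 8)

  # selecting it from a cap that contains those electrodes yields 8 channels
  cap <- tiny_bundle(n = 2, C = 4)
  cap$channel_names <- c("Fz", "Cz", "C3", "C4")
  sub <- select_channels(cap, montage(c("FZ", "cz")))
  expect_equal(dim(sub$signals)[1], 2)
})

test_that("fixation dataset assembly unions labels and splits", {
  pos <- split_dataset(tiny_bundle(n = 3, C = 2, L = 8), seed = 1)
  neg <- split_dataset(tiny_bundle(n = 4, C = 2, L = 8, seed = 7), seed = 2)
  fx <- build_fixation_dataset(pos, neg)
  expect_equal(n_epochs(fx), 7)
  expect_equal(mean(fx$labels), 3 / 7)
  expect_identical(fx$split, c(pos$split, neg$split))

  empty <- subset_epochs(neg, integer(0))
  all_pos <- build_fixation_dataset(pos, empty)
  expect_true(all(all_pos$labels == 1))

  bad <- tiny_bundle(n = 2, C = 3, L = 8)
  expect_error(build_fixation_dataset(pos, bad), "incompatible shapes")
})

test_that("splits are floor-based, deterministic and partition the data", {
  b <- split_dataset(tiny_bundle(n = 1000, C = 1, L = 2), seed = 3)
  expect_equal(as.integer(table(b$split)[c("train", "val", "test")]),
               c(700L, 150L, 150L))

  b7 <- split_dataset(tiny_bundle(n = 7, C = 1, L = 2), seed = 3)
  expect_equal(as.integer(table(b7$split)[c("train", "val", "test")]),
               c(5L, 1L, 1L))

  b2 <- split_dataset(tiny_bundle(n = 1000, C = 1, L = 2), seed = 3)
  expect_identical(b$split, b2$split)
  # every epoch in exactly one split
  expect_false(anyNA(b$split))

  expect_error(split_dataset(b, fractions = c(0.5, 0.5, 0.5)), "summing")
})

test_that("standardization uses training-split statistics only", {
  b <- split_dataset(tiny_bundle(n = 50, C = 3, L = 16), seed = 1)
  b$signals[2, , ] <- b$signals[2, , ] * 10 + 5
  st <- channel_stats(b)
  bs <- standardize_bundle(b, st)
  tr <- split_indices(b, "train")
  x2 <- bs$signals[2, , tr]
  expect_lt(abs(mean(x2)), 1e-10)
  expect_lt(abs(sd(as.numeric(x2)) - 1), 0.02)
  # statistics come from the training split, not from the whole bundle
  expect_equal(st$mu[2], mean(b$signals[2, , tr]))
})
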