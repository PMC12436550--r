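test_that("shape inference reproduces the published dimension table", {
  cfg <- nominal_config("model_b")
  expect_equal(cfg$T_len, 29)
  expect_equal(cfg$K, 128)
  expect_equal(cfg$H, 768)

  cfg_a <- nominal_config("model_a")
  expect_equal(cfg_a$C_prime, 6)
  expect_equal(cfg_a$K_prime, 768)

  # 8-channel montage: no spatial reduction is possible, C' = C = 8
  cfg_a8 <- model_config("model_a", C = 8, L = 500, K = 128, H = 768)
  expect_equal(cfg_a8$C_prime, 8)
  expect_equal(cfg_a8$K_prime, 1024)
  expect_equal(cfg_a8$T_len, 29)

  # T shrinks with the cropped length under the same kernel plan
  expect_equal(model_config("model_b", C = 129, L = 400, K = 8)$T_len, 23)
  expect_equal(model_config("model_b", C = 129, L = 200, K = 8)$T_len, 10)

  expect_error(model_config("model_b", C = 4, L = 8, K = 4), "too short")
  expect_error(model_config("model_b", C = 4, L = 128, K = 5,
                            transformer_heads = 2), "divide")
})

test_that("forward passes produce the declared intermediate shapes", {
  # checked on zero inputs: shapes must hold for every variant
  for (variant in c("model_b", "model_a", "model_a_tt", "model_a_st")) {
    cfg <- tiny_config(variant)
    m <- init_model(cfg, seed = 1)
    fw <- model_forward(m, array(0, c(12, 16, 2)))
    expect_equal(dim(fw$output), c(2L, 2L), info = variant)
  }

  cfg <- tiny_config("model_b")
  m <- init_model(cfg, seed = 1)
  fr <- eegaze:::conv1d_front_fwd(m$params, cfg, array(0, c(12, 16, 2)))
  expect_equal(dim(fr$out), c(cfg$K, 12 * 2, cfg$T_len))

  cfg_a <- tiny_config("model_a")
  ma <- init_model(cfg_a, seed = 1)
  fra <- eegaze:::conv2d_front_fwd(ma$params, cfg_a, array(0, c(12, 16, 2)))
  expect_equal(dim(fra$out), c(cfg_a$K, cfg_a$C_prime, cfg_a$T_len, 2))

  fwb <- model_forward(m, array(rnorm(12 * 16), c(12, 16, 1)),
                       want_attention = TRUE)
  expect_equal(dim(fwb$attention), c(13, 13, cfg$T_len, 1))
  expect_error(model_forward(m, array(0, c(12, 20, 1))), "does not match")
  expect_error(model_forward(init_model(tiny_config("model_a"), 1),
                             array(0, c(12, 16, 1)), want_attention = TRUE),
               "no spatial Transformer")
})

test_that("the 1-D front end treats channels independently", {
  cfg <- tiny_config("model_b", C = 6)
  m <- init_model(cfg, seed = 2)
  X <- array(rnorm(6 * 16 * 1), c(6, 16, 1))
  out1 <- eegaze:::conv1d_front_fwd(m$params, cfg, X)$out
  perm <- c(4, 1, 6, 3, 2, 5)
  out2 <- eegaze:::conv1d_front_fwd(m$params, cfg,
                                    X[perm, , , drop = FALSE])$out
  # sequence-batch axis is channel-major: permuting input rows permutes it
  expect_equal(out2[, , ], out1[, perm, ], tolerance = 1e-12)

  # a single-channel input runs through the same shared kernel plan
  cfg1 <- model_config("model_b", C = 1, L = 16, K = 4, n_blocks = 2,
                       transformer_layers = 1, transformer_heads = 2)
  m1 <- init_model(cfg1, seed = 2)
  fr1 <- eegaze:::conv1d_front_fwd(m1$params, cfg1, array(rnorm(16),
                                                          c(1, 16, 1)))
  expect_equal(dim(fr1$out), c(4, 1, cfg1$T_len))
})

test_that("attention rows are stochastic and uniform under zero queries", {
  cfg <- tiny_config("model_b", C = 4)
  m <- init_model(cfg, seed = 3)
  fw <- model_forward(m, array(rnorm(4 * 16 * 3), c(4, 16, 3)),
                      want_attention = TRUE)
  sums <- apply(fw$attention, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(fw$attention >= 0))

  # zero query projection forces constant scores, hence uniform rows
  m$params$encoder[[1]]$Wq[] <- 0
  m$params$encoder[[1]]$bq[] <- 0
  fw0 <- model_forward(m, array(rnorm(4 * 16), c(4, 16, 1)),
                       want_attention = TRUE)
  expect_equal(as.numeric(fw0$attention[1, , 1, 1]), rep(1 / 5, 5),
               tolerance = 1e-12)
})

test_that("model_b is channel-permutation invariant iff embeddings are off", {
  base <- tiny_config("model_b", C = 8)
  X <- array(rnorm(8 * 16 * 2), c(8, 16, 2))
  perm <- sample(8)

  cfg_off <- model_config("model_b", C = 8, L = 16, K = 4, H = 5,
                          n_blocks = 2, transformer_layers = 1,
                          transformer_heads = 2,
                          use_channel_embedding = FALSE)
  m_off <- init_model(cfg_off, seed = 4)
  y1 <- model_forward(m_off, X)$output
  y2 <- model_forward(m_off, X[perm, , , drop = FALSE])$output
  expect_lt(max(abs(y1 - y2)), 1e-5)

  m_on <- init_model(base, seed = 4)
  z1 <- model_forward(m_on, X)$output
  z2 <- model_forward(m_on, X[perm, , , drop = FALSE])$output
  expect_gt(max(abs(z1 - z2)), 1e-6)
})

test_that("LSTM summarizer handles degenerate and padded sequences", {
  set.seed(6)
  p <- eegaze:::lstm_init(3, 5)
  x1 <- matrix(rnorm(6), 3, 2)
  h1 <- eegaze:::lstm_fwd(p, list(x1))$h
  expect_equal(dim(h1), c(5L, 2L))
  # T = 1 equals a single cell step from the zero state
  Z <- p$Wx %*% x1 + p$b
  i <- eegaze:::sigmoid(Z[1:5, ]); f <- eegaze:::sigmoid(Z[6:10, ])
  g <- tanh(Z[11:15, ]); o <- eegaze:::sigmoid(Z[16:20, ])
  expect_equal(h1, o * tanh(i * g), tolerance = 1e-12)

  # zero-padding the sequence changes the output: no masking is applied
  h2 <- eegaze:::lstm_fwd(p, list(x1, matrix(0, 3, 2)))$h
  expect_gt(max(abs(h2 - h1)), 1e-8)
})

test_that("prediction heads are plain affine maps with documented links", {
  cfg <- tiny_config("model_b", head = "fixation")
  m <- init_model(cfg, seed = 7)
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  fw <- model_forward(m, array(rnorm(12 * 16), c(12, 16, 1)))
  expect_equal(eegaze:::sigmoid(as.numeric(fw$output)), 0.5)

  cfg_g <- tiny_config("model_b", head = "gaze")
  mg <- init_model(cfg_g, seed = 7)
  mg$params$head$W[] <- 0
  mg$params$head$b <- c(3.5, -2)
  fwg <- model_forward(mg, array(rnorm(12 * 16), c(12, 16, 1)))
  expect_equal(as.numeric(fwg$output), c(3.5, -2))

  # hand-computed affine output on a 2-unit summary
  W <- matrix(c(1, -1, 2, 0.5), 2, 2)
  expect_equal(as.numeric(eegaze:::linear_fwd(W, c(0.1, 0.2), c(2, 3))),
               as.numeric(W %*% c(2, 3) + c(0.1, 0.2)))
})

test_that("forward passes are deterministic", {
  for (variant in c("model_b", "model_a_st")) {
    m <- init_model(tiny_config(variant), seed = 8)
    X <- array(rnorm(12 * 16 * 2), c(12, 16, 2))
    expect_identical(model_forward(m, X)$output, model_forward(m, X)$output)
  }
})

test_that("analytic gradients match finite differences for every variant", {
  set.seed(42)
  eps <- 1e-5
  for (variant in c("model_b", "model_a", "model_a_tt", "model_a_st")) {
    cfg <- tiny_config(variant, head = "gaze")
    m <- init_model(cfg, seed = 7)
    B <- 2
    X <- array(rnorm(12 * 16 * B), c(12, 16, B))
    target <- matrix(rnorm(2 * B), 2, B)
    fw <- model_forward(m, X, want_cache = TRUE)
    ls <- eegaze:::loss_gaze(fw$output, target)
    g <- eegaze:::model_backward(m, fw, ls$dout)
    lossfn <- function(model) {
      eegaze:::loss_gaze(model_forward(model, X)$output, target)$loss
    }
    for (path in leaf_paths(m$params)) {
      leaf <- get_leaf(m$params, path)
      gleaf <- get_leaf(g, path)
      expect_false(is.null(gleaf),
                   info = paste(variant, paste(path, collapse = "/")))
      for (i in sample(length(leaf), min(2, length(leaf)))) {
        v <- leaf
        mp <- m
        v[i] <- leaf[i] + eps
        mp$params <- set_leaf(m$params, path, v)
        lp <- lossfn(mp)
        v[i] <- leaf[i] - eps
        mp$params <- set_leaf(m$params, path, v)
        lm_ <- lossfn(mp)
        num <- (lp - lm_) / (2 * eps)
        expect_equal(gleaf[i], num, tolerance = 1e-3,
                     info = paste(variant, paste(path, collapse = "/"), i))
      }
    }
  }
})

test_that("gradient reaches every trainable parameter", {
  set.seed(9)
  for (variant in c("model_b", "model_a", "model_a_tt", "model_a_st")) {
    cfg <- tiny_config(variant, head = "gaze")
    m <- init_model(cfg, seed = 11)
    X <- array(rnorm(12 * 16 * 4), c(12, 16, 4))
    fw <- model_forward(m, X, want_cache = TRUE)
    ls <- eegaze:::loss_gaze(fw$output, matrix(rnorm(8), 2, 4))
    g <- eegaze:::model_backward(m, fw, ls$dout)
    for (path in leaf_paths(m$params)) {
      gleaf <- get_leaf(g, path)
      expect_gt(max(abs(gleaf)), 0,
                label = paste(variant, paste(path, collapse = "/")))
    }
  }
})
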