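make_cell <- function(H = 2, E = 2, fill = 0) {
  Z <- matrix(fill, E, H)
  V <- matrix(fill, H, H)
  gru_params(W_z = Z, V_z = V, b_z = rep(fill, H),
             W_r = Z, V_r = V, b_r = rep(fill, H),
             W_C = Z, V_C = V, b_C = rep(fill, H))
}

test_that("the GRU cell honours its gating identities", {
  # all-zero parameters: sigma(0) = 0.5, tanh(0) = 0 -> h_t = 0.5 h_prev
  v <- c(0.8, -0.3)
  st <- gru_cell_step(c(1, 2), v, make_cell())
  expect_equal(st$z_t, c(0.5, 0.5))
  expect_equal(st$r_t, c(0.5, 0.5))
  expect_equal(st$C_hat_t, c(0, 0))
  expect_identical(st$h_t, 0.5 * v)

  # saturated update gate retains the old state
  p <- make_cell()
  p$b_z <- c(1000, 1000)
  st2 <- gru_cell_step(c(3, -2), v, p)
  expect_equal(st2$h_t, v, tolerance = 1e-6)

  # z forced to 0 adopts the candidate state
  p$b_z <- c(-1000, -1000)
  st3 <- gru_cell_step(c(3, -2), v, p)
  expect_equal(st3$h_t, st3$C_hat_t)
})

test_that("a two-unit step matches independent scalar arithmetic", {
  x <- c(1, -1)
  h <- c(0.5, -0.25)
  p <- gru_params(W_z = rbind(c(1, 0), c(0, 1)),
                  V_z = rbind(c(1, 1), c(0, 1)),
                  b_z = c(0.5, -0.5),
                  W_r = rbind(c(0, 1), c(1, 0)),
                  V_r = rbind(c(1, 0), c(1, 1)),
                  b_r = c(-1, 1),
                  W_C = rbind(c(2, 0), c(0, 2)),
                  V_C = rbind(c(1, -1), c(1, 0)),
                  b_C = c(0, 0.1))
  # spelled out scalar-by-scalar, independently of any matrix code
  sig <- function(a) 1 / (1 + exp(-a))
  z1 <- sig(1 * 1 + (-1) * 0 + 0.5 * 1 + (-0.25) * 0 + 0.5)
  z2 <- sig(1 * 0 + (-1) * 1 + 0.5 * 1 + (-0.25) * 1 - 0.5)
  r1 <- sig(1 * 0 + (-1) * 1 + 0.5 * 1 + (-0.25) * 1 - 1)
  r2 <- sig(1 * 1 + (-1) * 0 + 0.5 * 0 + (-0.25) * 1 + 1)
  g1 <- r1 * 0.5
  g2 <- r2 * (-0.25)
  c1 <- tanh(1 * 2 + (-1) * 0 + g1 * 1 + g2 * 1 + 0)
  c2 <- tanh(1 * 0 + (-1) * 2 + g1 * (-1) + g2 * 0 + 0.1)
  h1 <- z1 * 0.5 + (1 - z1) * c1
  h2 <- z2 * (-0.25) + (1 - z2) * c2
  st <- gru_cell_step(x, h, p)
  expect_equal(st$z_t, c(z1, z2), tolerance = 1e-10)
  expect_equal(st$r_t, c(r1, r2), tolerance = 1e-10)
  expect_equal(st$C_hat_t, c(c1, c2), tolerance = 1e-10)
  expect_equal(st$h_t, c(h1, h2), tolerance = 1e-10)
})

test_that("h_t lies componentwise between h_prev and the candidate state", {
  for (i in 1:20) {
    st <- withr::with_seed(200 + i, {
      p <- gru_params(W_z = matrix(rnorm(6), 3), V_z = matrix(rnorm(4), 2),
                      b_z = rnorm(2),
                      W_r = matrix(rnorm(6), 3), V_r = matrix(rnorm(4), 2),
                      b_r = rnorm(2),
                      W_C = matrix(rnorm(6), 3), V_C = matrix(rnorm(4), 2),
                      b_C = rnorm(2))
      gru_cell_step(rnorm(3), rnorm(2), p)
    })
    lo <- pmin(st$h_prev, st$C_hat_t)
    hi <- pmax(st$h_prev, st$C_hat_t)
    expect_true(all(st$h_t >= lo - 1e-12 & st$h_t <= hi + 1e-12))
    expect_true(all(st$z_t > 0 & st$z_t < 1))
    expect_true(all(abs(st$C_hat_t) < 1))
  }
})

test_that("the batched forward pass agrees with iterating the single cell", {
  cfg <- backbone_config(vocab_size = 10, embedding_dim = 3, gru_units = 4,
                         dense_units = 5, dropout_rate = 0,
                         latent_layer_index = 2)
  m <- build_backbone(cfg, seed = 31)
  tokens <- withr::with_seed(32, matrix(sample(0:10, 6 * 9, TRUE), 6, 9))
  lengths <- c(9L, 9L, 5L, 2L, 9L, 7L)
  for (i in seq_len(6)) {
    if (lengths[i] < 9) tokens[i, (lengths[i] + 1):9] <- 0L
  }
  batch_h <- gmean:::rnn_direction_forward(m$params, cfg, "f", tokens,
                                           lengths)$h
  for (i in seq_len(6)) {
    ref <- gru_reference_final_state(m$params, m$params$emb,
                                     tokens[i, ], lengths[i])
    expect_equal(batch_h[i, ], ref, tolerance = 1e-12)
  }
})

test_that("the backbone architecture has the configured layer widths", {
  cfg <- backbone_config(vocab_size = 16)
  m <- build_backbone(cfg, seed = 1)
  expect_equal(ncol(m$params$Uc_f), 200L)
  expect_equal(dim(m$params$Wd_1), c(200L, 128L))
  expect_equal(dim(m$params$Wd_2), c(128L, 64L))
  expect_equal(dim(m$params$Wd_3), c(64L, 32L))
  expect_equal(dim(m$params$Wd_4), c(32L, 16L))
  expect_equal(dim(m$params$W_out), c(16L, 1L))

  # parameter count equals the closed-form per-layer sum
  E <- 32; H <- 200; V <- 16
  expected <- (V + 1) * E +                      # embedding
    (E * 3 * H + H * 2 * H + H * H + 3 * H) +    # GRU gates
    (200 * 128 + 128) + (128 * 64 + 64) +        # dense stack
    (64 * 32 + 32) + (32 * 16 + 16) +
    (16 * 1 + 1)                                 # sigmoid head
  expect_equal(count_parameters(m), expected)

  expect_error(backbone_config(vocab_size = 16, latent_layer_index = 6),
               "1..5")
})

test_that("outputs are strictly inside (0, 1) for every backbone kind", {
  tokens <- withr::with_seed(21, matrix(sample(1:8, 5 * 12, TRUE), 5, 12))
  for (kind in c("gru", "bigru", "lstm", "bilstm")) {
    cfg <- backbone_config(vocab_size = 8, embedding_dim = 4, gru_units = 6,
                           dense_units = c(5, 4), latent_layer_index = 2,
                           backbone_kind = kind)
    m <- build_backbone(cfg, seed = 3)
    p <- gmean:::forward_backbone(m, tokens, rep(12L, 5))$prob
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("analytic gradients match finite differences for all kinds", {
  ns <- asNamespace("gmean")
  for (kind in c("gru", "bigru", "lstm", "bilstm")) {
    cfg <- backbone_config(vocab_size = 6, embedding_dim = 4, gru_units = 3,
                           dense_units = c(5, 4), dropout_rate = 0,
                           latent_layer_index = 2, backbone_kind = kind)
    m <- build_backbone(cfg, seed = 11)
    # keep every relu pre-activation away from its kink
    m$params <- withr::with_seed(12, lapply(m$params, function(p) {
      p + stats::runif(length(p), 0.01, 0.05)
    }))
    tokens <- withr::with_seed(13, matrix(sample(0:6, 5 * 7, TRUE), 5, 7))
    lengths <- c(7L, 7L, 4L, 2L, 7L)
    for (i in 1:5) if (lengths[i] < 7) tokens[i, (lengths[i] + 1):7] <- 0L
    y <- c(1, 0, 1, 0, 1)
    fwd <- ns$forward_backbone(m, tokens, lengths, training = TRUE)
    grads <- ns$backward_backbone(m, fwd, y)
    loss_at <- function(params) {
      m2 <- m
      m2$params <- params
      ns$bce_loss(ns$forward_backbone(m2, tokens, lengths, FALSE)$prob, y)
    }
    eps <- 1e-6
    for (nm in names(grads)) {
      idx <- withr::with_seed(14, sample(length(m$params[[nm]]),
                                         min(4, length(m$params[[nm]]))))
      for (j in idx) {
        pp <- m$params; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- m$params; pm[[nm]][j] <- pm[[nm]][j] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(as.numeric(grads[[nm]][j]), num, tolerance = 1e-4,
                     label = sprintf("%s gradient of %s[%d]", kind, nm, j))
      }
    }
  }
})

test_that("one epoch on a batch reduces its training loss almost surely", {
  ns <- asNamespace("gmean")
  full <- tiny_tokenized(n_per_class = 40, seq_length = 25, seed = 51)
  keep <- c(1:8, 41:48)  # one balanced 16-sequence batch
  batch <- full
  batch$tokens <- full$tokens[keep, ]
  batch$lengths <- full$lengths[keep]
  batch$labels <- full$labels[keep]
  batch$ids <- full$ids[keep]
  cfg <- backbone_config(vocab_size = 16, embedding_dim = 8, gru_units = 8,
                         dense_units = c(8, 4), latent_layer_index = 2,
                         dropout_rate = 0, max_timescale = 25)
  improved <- vapply(1:20, function(s) {
    m <- build_backbone(cfg, seed = s)
    init <- ns$bce_loss(predict_proba(m, batch), batch$labels)
    tc <- train_config(epochs = 1, batch_size = 16,
                       early_stopping_patience = 0, seed = s)
    m2 <- train_supervised(m, batch, batch, tc)
    after <- ns$bce_loss(predict_proba(m2, batch), batch$labels)
    after < init
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("early stopping halts a stalled monitor at best + patience", {
  plan <- gmean:::early_stopping_plan(rep(0.7, 10), patience = 3)
  expect_equal(plan$best_epoch, 1L)
  expect_equal(plan$stop_epoch, 4L)  # exactly patience epochs after the best

  plan2 <- gmean:::early_stopping_plan(c(0.9, 0.5, 0.6, 0.6, 0.6, 0.6),
                                       patience = 3)
  expect_equal(plan2$best_epoch, 2L)
  expect_equal(plan2$stop_epoch, 5L)

  improving <- gmean:::early_stopping_plan(seq(1, 0.1, by = -0.1),
                                           patience = 3)
  expect_equal(improving$stop_epoch, 10L)

  # the training loop obeys the same contract: constant validation data
  # with a saturated model stalls and stops early
  data <- tiny_tokenized(n_per_class = 20, seq_length = 20, seed = 61)
  cfg <- backbone_config(vocab_size = 16, embedding_dim = 4, gru_units = 4,
                         dense_units = 4, dropout_rate = 0,
                         latent_layer_index = 2)
  m <- build_backbone(cfg, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)  # frozen at sigma(0)
  tc <- train_config(epochs = 30, batch_size = 64,
                     early_stopping_patience = 4, seed = 2)
  m2 <- train_supervised(m, data, data, tc)
  expect_equal(nrow(m2$history), 1L + 4L)

  expect_error(train_config(epochs = 3, early_stopping_patience = 5),
               "smaller than epochs")
})

test_that("a separable motif dataset is learned to high training accuracy", {
  d <- generate_synthetic(synthetic_config(n_per_class = 250,
                                           seq_length = 40, seed = 71))
  sp <- split_dataset(d, seed = 72)
  v <- build_vocabulary(sp$train, kmer_config(2))
  tr <- encode_dataset(sp$train, v)
  va <- encode_dataset(sp$validation, v)
  cfg <- backbone_config(vocab_size = 16, gru_units = 32,
                         dense_units = c(16, 8), latent_layer_index = 2,
                         max_timescale = 40)
  m <- build_backbone(cfg, seed = 73)
  tc <- train_config(epochs = 35, batch_size = 32, learning_rate = 3e-3,
                     early_stopping_patience = 34, seed = 74)
  m2 <- train_supervised(m, tr, va, tc)
  expect_gte(max(m2$history$accuracy), 0.95)
  expect_lte(nrow(m2$history), 35L)
})

test_that("latent extraction is deterministic with the configured width", {
  data <- tiny_tokenized(n_per_class = 5, seq_length = 30, seed = 81)
  m <- build_backbone(backbone_config(vocab_size = 16), seed = 82)
  lat <- extract_latent(m, data)
  expect_equal(dim(lat), c(10L, 32L))  # default latent layer -> width 32
  expect_identical(lat, extract_latent(m, data))  # bitwise repeatable

  # a duplicated input row maps to an identical latent row
  dup <- data
  dup$tokens <- data$tokens[c(1, 1, 2), ]
  dup$lengths <- data$lengths[c(1, 1, 2)]
  dup$labels <- data$labels[c(1, 1, 2)]
  lat2 <- extract_latent(m, dup)
  expect_identical(lat2[1, ], lat2[2, ])

  # other layers select their own widths
  expect_equal(ncol(extract_latent(m, data, layer_index = 1)), 200L)
  expect_equal(ncol(extract_latent(m, data, layer_index = 5)), 16L)
  expect_error(extract_latent(m, data, layer_index = 9), "1..5")

  # vocabulary mismatch is a contract error
  other <- data
  other$vocab <- vocabulary_from_map(c("aa", "cc"))
  other$tokens <- matrix(1L, 2, 3)
  m$vocab <- data$vocab
  expect_error(extract_latent(m, other), "mismatch")
})

test_that("checkpoints round-trip weights, vocabulary and predictions", {
  data <- tiny_tokenized(n_per_class = 15, seq_length = 25, seed = 91)
  cfg <- backbone_config(vocab_size = 16, embedding_dim = 4, gru_units = 6,
                         dense_units = c(6, 4), latent_layer_index = 2)
  m <- build_backbone(cfg, seed = 92)
  tc <- train_config(epochs = 2, batch_size = 16,
                     early_stopping_patience = 1, seed = 93)
  m2 <- train_supervised(m, data, data, tc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_backbone(m2, path)
  back <- load_backbone(path)
  expect_identical(predict_proba(back, data), predict_proba(m2, data))
  expect_identical(back$vocab$kmers, m2$vocab$kmers)
  expect_equal(back$history, m2$history)
})
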